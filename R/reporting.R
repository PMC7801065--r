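#' Render the tumor-type quasi H-score heat map
#'
#' Genes by tumor types, continuous color scale fixed to \[0, 300\];
#' undefined (unassayed) cells are drawn in a distinct neutral fill. A TSV
#' sidecar of the exact plotted matrix is written next to the image
#' (`<image>_data.tsv`), so figure content is testable without pixel
#' comparison.
#'
#' @param score_matrix Quasi H-score matrix ([quasi_h_matrix()]).
#' @param out_path Output image path (extension chooses the device, e.g.
#'   `.png`).
#' @param gene_order,tumor_order Optional row/column orders; default the
#'   matrix order.
#' @param width,height Device size in inches.
#' @return Invisible list with `image` and `sidecar` paths.
#' @export
render_score_heatmap <- function(score_matrix, out_path, gene_order = NULL,
                                 tumor_order = NULL, width = 8,
                                 height = NULL) {
  if (is.null(dim(score_matrix)) || nrow(score_matrix) == 0 ||
      ncol(score_matrix) == 0) {
    stop("score matrix is empty", call. = FALSE)
  }
  if (is.null(gene_order)) gene_order <- rownames(score_matrix)
  if (is.null(tumor_order)) tumor_order <- colnames(score_matrix)
  mat <- score_matrix[gene_order, tumor_order, drop = FALSE]
  df <- data.frame(
    gene = factor(rep(rownames(mat), times = ncol(mat)),
                  levels = rev(rownames(mat))),
    tumor = factor(rep(colnames(mat), each = nrow(mat)),
                   levels = colnames(mat)),
    score = as.vector(mat)
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tumor, y = .data$gene,
                                         fill = .data$score)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient(low = "#fff5eb", high = "#7f2704",
                                 limits = c(0, 300),
                                 na.value = "grey70",
                                 name = "Quasi H-score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (is.null(height)) height <- max(2, 0.18 * nrow(mat) + 1.5)
  ggplot2::ggsave(out_path, gg, width = width, height = height, dpi = 150)
  sidecar <- sidecar_path(out_path)
  write_matrix_tsv(mat, sidecar)
  invisible(list(image = out_path, sidecar = sidecar))
}

#' Render the normal-tissue ordinal-level heat map
#'
#' Genes by the 45 normal tissues on the discrete four-level scale, with
#' per-tissue aggregation as the maximum level over cell types. Writes a
#' TSV sidecar of the plotted (gene, tissue, level) matrix.
#'
#' @param normal Long normal-tissue table (`gene_id`, `tissue`,
#'   `cell_type`, `level`).
#' @param out_path Output image path.
#' @param gene_order Genes to plot, in row order; default all genes in the
#'   table.
#' @param tissue_order Column order; default [normal_tissues()].
#' @inheritParams render_score_heatmap
#' @return Invisible list with `image` and `sidecar` paths.
#' @export
render_normal_heatmap <- function(normal, out_path, gene_order = NULL,
                                  tissue_order = normal_tissues(),
                                  width = 10, height = NULL) {
  if (is.null(gene_order)) gene_order <- unique(normal$gene_id)
  if (length(gene_order) == 0) stop("no genes to plot", call. = FALSE)
  mat <- normal_level_matrix(normal, gene_order, tissue_order)
  lv <- c("not_detected", "low", "medium", "high")
  df <- data.frame(
    gene = factor(rep(rownames(mat), times = ncol(mat)),
                  levels = rev(rownames(mat))),
    tissue = factor(rep(colnames(mat), each = nrow(mat)),
                    levels = colnames(mat)),
    level = factor(as.vector(mat), levels = lv)
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$gene,
                                         fill = .data$level)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_manual(
      values = c(not_detected = "#f7f7f7", low = "#fee391",
                 medium = "#fe9929", high = "#cc4c02"),
      na.value = "grey70", drop = FALSE, name = "IHC level"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  if (is.null(height)) height <- max(2, 0.18 * nrow(mat) + 1.8)
  ggplot2::ggsave(out_path, gg, width = width, height = height, dpi = 150)
  sidecar <- sidecar_path(out_path)
  write_matrix_tsv(mat, sidecar)
  invisible(list(image = out_path, sidecar = sidecar))
}

#' Per-tissue ordinal-level matrix (maximum over cell types)
#'
#' @inheritParams render_normal_heatmap
#' @return Character matrix of canonical level names, genes x tissues; `NA`
#'   where a tissue was not annotated for a gene.
#' @export
normal_level_matrix <- function(normal, gene_order,
                                tissue_order = normal_tissues()) {
  w <- ihc_level_weights()
  mat <- matrix(NA_character_, nrow = length(gene_order),
                ncol = length(tissue_order),
                dimnames = list(gene_order, tissue_order))
  sub <- normal[normal$gene_id %in% gene_order &
                  normal$tissue %in% tissue_order, , drop = FALSE]
  if (nrow(sub) > 0) {
    agg <- stats::aggregate(w[sub$level],
                            by = list(gene_id = sub$gene_id,
                                      tissue = sub$tissue), FUN = max)
    mat[cbind(match(agg$gene_id, gene_order),
              match(agg$tissue, tissue_order))] <- names(w)[agg$x + 1]
  }
  mat
}

#' Write the screening audit table
#'
#' @param audit Audit table from [run_screening()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_audit_tsv <- function(audit, path) {
  write_tsv(audit, path)
}

#' Write the ranked candidate table
#'
#' One row per candidate with the validation flags and priority columns.
#'
#' @param result A [run_pipeline()] result.
#' @param genes Gene table (for symbols).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(result, genes, path) {
  prio <- result$priorities
  if (is.null(prio)) {
    prio <- data.frame(gene_id = character(0), max_quasi_h = numeric(0),
                       n_tumors_ge_cutoff = integer(0),
                       n_normal_high_or_medium = integer(0),
                       n_normal_high = integer(0), stringsAsFactors = FALSE)
  }
  val <- result$validation[match(prio$gene_id, result$validation$gene_id), ,
                           drop = FALSE]
  out <- data.frame(
    gene_id = prio$gene_id,
    gene_symbol = genes$gene_symbol[match(prio$gene_id, genes$gene_id)],
    rna_consistent = val$rna_consistent,
    literature_conform = val$literature_conform,
    membranous_staining = val$membranous_staining,
    is_candidate = val$is_candidate,
    max_quasi_h = round(prio$max_quasi_h, 1),
    n_tumors_ge_cutoff = prio$n_tumors_ge_cutoff,
    n_normal_high_or_medium = prio$n_normal_high_or_medium,
    n_normal_high = prio$n_normal_high,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

#' Write a score matrix as TSV (genes x tumor types)
#'
#' @param mat Matrix with row and column names.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

sidecar_path <- function(out_path) {
  paste0(tools::file_path_sans_ext(out_path), "_data.tsv")
}
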