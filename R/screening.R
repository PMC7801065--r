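#' Quasi H-score of one tumor-type patient cohort
#'
#' Cohort-level analogue of the IHC H-score, on the same 0--300 scale:
#'
#' \deqn{Q = 1 \cdot \%low + 2 \cdot \%medium + 3 \cdot \%high}
#'
#' where the percentages are over all assayed patients of one tumor type,
#' including those with no detected staining (weight 0). The score is 300
#' only when every patient is in the high category and 0 only when no
#' patient is above not-detected. A cohort with zero assayed patients has an
#' undefined score (`NA`), never 0: absence of assay is not evidence of
#' absence.
#'
#' @param n_high,n_medium,n_low,n_not_detected Non-negative integer patient
#'   counts; vectorized.
#' @return Numeric vector of scores in \[0, 300\], `NA` where the total
#'   count is zero.
#' @export
quasi_h_score <- function(n_high, n_medium, n_low, n_not_detected) {
  counts <- cbind(n_high, n_medium, n_low, n_not_detected)
  if (any(counts < 0, na.rm = TRUE)) {
    stop("negative patient counts are not allowed", call. = FALSE)
  }
  total <- n_high + n_medium + n_low + n_not_detected
  score <- 100 * (1 * n_low + 2 * n_medium + 3 * n_high) / total
  score[total == 0] <- NA_real_
  score
}

#' Quasi H-score matrix from a pathology count table
#'
#' @param pathology data.frame as returned by [read_pathology_counts()].
#' @param tumor_order Column order; defaults to [tumor_types()] restricted
#'   to the tumor types present, preserving that canonical order.
#' @return Numeric matrix, genes x tumor types, with `NA` for (gene, tumor)
#'   cells that were never assayed (absent rows or zero-total rows).
#' @export
quasi_h_matrix <- function(pathology, tumor_order = NULL) {
  genes <- unique(pathology$gene_id)
  tumors <- unique(pathology$tumor_type)
  if (is.null(tumor_order)) {
    tumor_order <- c(intersect(tumor_types(), tumors),
                     setdiff(tumors, tumor_types()))
  }
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(tumor_order),
                dimnames = list(genes, tumor_order))
  score <- quasi_h_score(pathology$n_high, pathology$n_medium,
                         pathology$n_low, pathology$n_not_detected)
  keep <- pathology$tumor_type %in% tumor_order
  mat[cbind(match(pathology$gene_id[keep], genes),
            match(pathology$tumor_type[keep], tumor_order))] <- score[keep]
  mat
}

#' Partition genes by protein-level evidence
#'
#' @param genes Gene record table with `gene_id` and `has_protein_evidence`.
#' @return List with `retained` and `excluded` gene tables (exhaustive,
#'   disjoint partition).
#' @export
filter_protein_evidence <- function(genes) {
  keep <- genes$has_protein_evidence
  list(retained = genes[keep, , drop = FALSE],
       excluded = genes[!keep, , drop = FALSE])
}

#' Exclude genes highly expressed in critical normal tissues
#'
#' A gene is excluded iff its maximum ordinal level over all cell types
#' within any critical tissue is `high`; medium expression never excludes.
#' Aggregation is the maximum over cell types within a tissue, because the
#' exclusion operates at tissue granularity while annotation is per cell
#' type.
#'
#' @param gene_ids Character vector of gene ids to partition.
#' @param normal Long normal-tissue table (`gene_id`, `tissue`, `cell_type`,
#'   `level`).
#' @param critical Character vector of critical tissue names; defaults to
#'   the 13-tissue set of [critical_tissues()].
#' @return List with `retained` and `excluded` character vectors.
#' @export
filter_critical_normal <- function(gene_ids, normal,
                                   critical = critical_tissues()) {
  check_tissue_names(normal$tissue)
  check_tissue_names(critical)
  hit <- unique(normal$gene_id[
    normal$level == "high" & normal$tissue %in% critical
  ])
  excluded <- intersect(gene_ids, hit)
  list(retained = setdiff(gene_ids, excluded), excluded = excluded)
}

#' Threshold filter on the quasi H-score matrix
#'
#' A gene is retained iff it has a defined score greater than or equal to
#' the cutoff in at least one tumor type; the comparison is inclusive, and
#' undefined (`NA`) scores never satisfy it.
#'
#' @param score_matrix Matrix from [quasi_h_matrix()].
#' @param cutoff Score threshold in (0, 300\]; default 150.
#' @return List with `retained` (character vector of gene ids), `max_score`
#'   (named per-gene maximum defined score, `NA` if none defined) and
#'   `n_ge_cutoff` (named per-gene count of tumor types at or above the
#'   cutoff).
#' @export
threshold_filter <- function(score_matrix, cutoff = 150) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1,
            cutoff > 0, cutoff <= 300)
  max_score <- apply(score_matrix, 1, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  n_ge <- apply(score_matrix, 1, function(x) sum(!is.na(x) & x >= cutoff))
  list(
    retained = rownames(score_matrix)[!is.na(max_score) &
                                        max_score >= cutoff],
    max_score = max_score,
    n_ge_cutoff = n_ge
  )
}

#' Intersect a gene set with the predicted surfaceome
#'
#' @param gene_ids Character vector of gene ids.
#' @param surfaceome Character vector of surfaceome member ids.
#' @return List with `retained` (members) and `excluded` (non-members).
#' @export
surfaceome_filter <- function(gene_ids, surfaceome) {
  list(retained = intersect(gene_ids, surfaceome),
       excluded = setdiff(gene_ids, surfaceome))
}

#' Run the full screening funnel
#'
#' Executes the five screening stages in order — membrane class,
#' protein-level evidence, critical-normal-tissue exclusion, quasi H-score
#' threshold, surfaceome intersection — and records an audit trail of gene
#' counts in and out of every stage.
#'
#' @param dataset List with components `genes`, `normal`, `pathology`,
#'   `surfaceome` (as produced by the readers or [simulate_dataset()]).
#' @param cutoff Quasi H-score threshold; default 150.
#' @param critical Critical tissue set; default [critical_tissues()].
#' @return List with:
#'   \describe{
#'     \item{potential}{character vector of surviving (potential target)
#'       gene ids, in stable gene-id order.}
#'     \item{scores}{quasi H-score matrix for the genes entering the
#'       threshold stage.}
#'     \item{audit}{data.frame `stage`, `n_in`, `n_out`, `excluded`
#'       (semicolon-collapsed gene ids), with telescoping counts.}
#'   }
#' @export
run_screening <- function(dataset, cutoff = 150,
                          critical = critical_tissues()) {
  genes <- dataset$genes
  stopifnot(all(c("gene_id", "is_membrane", "has_protein_evidence") %in%
                  names(genes)))
  unknown <- setdiff(dataset$pathology$gene_id, genes$gene_id)
  if (length(unknown) > 0) {
    stop("pathology table references unknown gene id(s): ",
         paste(sQuote(utils::head(unknown, 5)), collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(genes$gene_id)
  audit <- list()
  note <- function(stage, n_in, retained, excluded) {
    audit[[length(audit) + 1]] <<- data.frame(
      stage = stage, n_in = n_in, n_out = length(retained),
      excluded = paste(sort(excluded), collapse = ";"),
      stringsAsFactors = FALSE
    )
    retained
  }

  membrane <- genes$gene_id[genes$is_membrane]
  ids <- note("membrane_class", length(ids), sort(intersect(ids, membrane)),
              setdiff(ids, membrane))

  ev <- filter_protein_evidence(genes[match(ids, genes$gene_id), ,
                                      drop = FALSE])
  ids <- note("protein_evidence", length(ids), sort(ev$retained$gene_id),
              ev$excluded$gene_id)

  cn <- filter_critical_normal(ids, dataset$normal, critical)
  ids <- note("critical_normal", length(ids), sort(cn$retained),
              cn$excluded)

  path_sub <- dataset$pathology[dataset$pathology$gene_id %in% ids, ,
                                drop = FALSE]
  scores <- quasi_h_matrix(path_sub)
  # genes with no pathology rows at all have all-undefined scores
  missing <- setdiff(ids, rownames(scores))
  if (length(missing) > 0) {
    scores <- rbind(scores, matrix(
      NA_real_, nrow = length(missing), ncol = ncol(scores),
      dimnames = list(missing, colnames(scores))
    ))
  }
  scores <- scores[ids, , drop = FALSE]
  th <- threshold_filter(scores, cutoff)
  ids <- note("quasi_h_threshold", length(ids), sort(th$retained),
              setdiff(ids, th$retained))

  sf <- surfaceome_filter(ids, dataset$surfaceome)
  ids <- note("surfaceome", length(ids), sort(sf$retained), sf$excluded)

  audit <- do.call(rbind, audit)
  rownames(audit) <- NULL
  list(potential = ids, scores = scores, audit = audit)
}

#' Stage at which each gene left the funnel
#'
#' @param audit Audit table from [run_screening()].
#' @return Named character vector: for every excluded gene id, the name of
#'   the stage that removed it.
#' @export
exit_stages <- function(audit) {
  out <- character(0)
  for (i in seq_len(nrow(audit))) {
    ex <- strsplit(audit$excluded[i], ";", fixed = TRUE)[[1]]
    ex <- ex[nzchar(ex)]
    out[ex] <- audit$stage[i]
  }
  out
}
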