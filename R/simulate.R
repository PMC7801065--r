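#' Ground-truth gene classes of the synthetic generator
#'
#' Each generated gene is planted to violate exactly one screening or
#' validation rule and to pass all rules applied before it:
#' \describe{
#'   \item{candidate}{passes every stage.}
#'   \item{non_membrane}{not in the predicted-membrane-protein class.}
#'   \item{no_evidence}{membrane, but no protein-level (IHC) evidence.}
#'   \item{critical_normal_high}{high expression in >= 1 of the 13 critical
#'     normal tissues.}
#'   \item{low_score}{quasi H-score below the cutoff in every tumor type.}
#'   \item{non_surface_high}{scores at or above the cutoff somewhere but is
#'     not in the predicted surfaceome.}
#'   \item{fails_rna}{surface, above the cutoff, but IHC--RNA discordant.}
#'   \item{fails_literature}{fails only the literature-conformity flag.}
#'   \item{fails_membranous}{fails only the membranous-staining verdict.}
#' }
#'
#' @return Character vector of the nine class labels.
#' @export
gene_classes <- function() {
  c("candidate", "non_membrane", "no_evidence", "critical_normal_high",
    "low_score", "non_surface_high", "fails_rna", "fails_literature",
    "fails_membranous")
}

#' Configuration of the synthetic HPA-shaped dataset generator
#'
#' @param n_genes_per_class Named integer vector, one entry per class of
#'   [gene_classes()] (missing classes default to 0); default 5 of each.
#' @param tumors Tumor-type vocabulary; default the 20 of [tumor_types()].
#' @param tissues Normal-tissue vocabulary; default the 45 of
#'   [normal_tissues()].
#' @param critical Critical-tissue subset; default [critical_tissues()].
#' @param patients_per_tumor Patients assayed per (gene, tumor type);
#'   default 12, typical of HPA pathology cohorts.
#' @param rna_concordance Target Spearman correlation between quasi
#'   H-scores and FPKM for IHC--RNA concordant genes, in \[-1, 1\]; default
#'   0.8. Discordant (`fails_rna`) genes are generated at 0.
#' @param missing_cell_rate Probability that a non-designated (gene, tumor)
#'   pathology cell is unassayed (zero-total row, undefined score);
#'   default 0.05.
#' @param cutoff Screening score cutoff the planted classes straddle;
#'   default 150.
#' @param seed Integer seed; same config and seed give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes_per_class = NULL, tumors = tumor_types(),
                       tissues = normal_tissues(),
                       critical = critical_tissues(),
                       patients_per_tumor = 12, rna_concordance = 0.8,
                       missing_cell_rate = 0.05, cutoff = 150, seed = 1) {
  counts <- stats::setNames(rep(5L, length(gene_classes())), gene_classes())
  if (!is.null(n_genes_per_class)) {
    unknown <- setdiff(names(n_genes_per_class), gene_classes())
    if (length(unknown) > 0) {
      stop("unknown gene class(es): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    counts[] <- 0L
    counts[names(n_genes_per_class)] <- as.integer(n_genes_per_class)
  }
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (patients_per_tumor < 1) {
    stop("patients_per_tumor must be >= 1", call. = FALSE)
  }
  if (rna_concordance < -1 || rna_concordance > 1) {
    stop("rna_concordance must be in [-1, 1]", call. = FALSE)
  }
  if (!all(critical %in% tissues)) {
    stop("critical tissues must be a subset of the tissue vocabulary",
         call. = FALSE)
  }
  structure(
    list(n_genes_per_class = counts, tumors = tumors, tissues = tissues,
         critical = critical, patients_per_tumor = patients_per_tumor,
         rna_concordance = rna_concordance,
         missing_cell_rate = missing_cell_rate, cutoff = cutoff,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# ordinal-level sampling probabilities, in (high, medium, low, nd) order
sim_probs <- list(
  hot = c(high = 0.70, medium = 0.20, low = 0.05, not_detected = 0.05),
  background = c(high = 0.05, medium = 0.15, low = 0.30, not_detected = 0.50)
)

# draw patient counts for one (gene, tumor) cell; `constraint` keeps the
# planted classes on the intended side of the cutoff deterministically
draw_counts <- function(n, probs, cutoff, constraint = c("none", "ge", "lt")) {
  constraint <- match.arg(constraint)
  for (i in 1:1000) {
    x <- stats::rmultinom(1, n, probs)[, 1]
    s <- quasi_h_score(x[["high"]], x[["medium"]], x[["low"]],
                       x[["not_detected"]])
    if (constraint == "none" ||
        (constraint == "ge" && !is.na(s) && s >= cutoff) ||
        (constraint == "lt" && (is.na(s) || s < cutoff))) {
      return(x)
    }
  }
  stop("could not satisfy score constraint after 1000 draws", call. = FALSE)
}

cell_type_pool <- c(
  "glandular cells", "squamous epithelial cells", "endothelial cells",
  "macrophages", "smooth muscle cells", "epidermal cells", "hepatocytes",
  "cells in tubules", "myocytes", "hematopoietic cells"
)

#' Generate a seeded, ground-truth-labeled HPA-shaped dataset
#'
#' Emulates the four pipeline inputs (gene/normal-tissue table, pathology
#' counts, surfaceome membership, FPKM table) plus curated validation
#' flags, with every gene planted to exit the funnel at the stage its class
#' names (see [gene_classes()]). Threshold-straddling is enforced by
#' rejection sampling, not left to chance: designated tumors of
#' above-cutoff classes are redrawn until their realized quasi H-score
#' reaches the cutoff, below-cutoff classes until every tumor stays under
#' it, and FPKM vectors until the default RNA-consistency rule gives the
#' planted verdict.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `normal`, `pathology`, `surfaceome`, `fpkm`,
#'   `flags`, `truth` (data.frame `gene_id`, `class`) and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  counts <- config$n_genes_per_class
  classes <- rep(names(counts), counts)
  n <- length(classes)
  truth <- data.frame(
    gene_id = sprintf("ENSG%011d", seq_len(n)),
    gene_symbol = sprintf("SIM%04d", seq_len(n)),
    class = classes,
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene_id = truth$gene_id,
    gene_symbol = truth$gene_symbol,
    is_membrane = classes != "non_membrane",
    has_protein_evidence = classes != "no_evidence",
    stringsAsFactors = FALSE
  )

  hot_classes <- c("candidate", "non_surface_high", "fails_rna",
                   "fails_literature", "fails_membranous")
  concordant_pass <- c("candidate", "fails_literature", "fails_membranous")
  fpkm_tumors <- intersect(config$tumors, fpkm_tumor_types())

  normal <- list()
  pathology <- list()
  fpkm <- list()
  surface <- character(0)

  for (i in seq_len(n)) {
    cls <- classes[i]
    gid <- truth$gene_id[i]

    # --- normal-tissue profile -------------------------------------------
    if (genes$has_protein_evidence[i]) {
      rows <- list()
      hot_critical <- if (cls == "critical_normal_high") {
        sample(config$critical, sample(1:2, 1))
      } else {
        character(0)
      }
      for (tis in config$tissues) {
        n_ct <- 1L + stats::rbinom(1, 1, 0.4)
        cts <- sample(cell_type_pool, n_ct)
        lv <- sample(c("not_detected", "low", "medium", "high"), n_ct,
                     replace = TRUE, prob = c(0.50, 0.30, 0.15, 0.05))
        if (tis %in% config$critical) {
          # never high in critical tissues unless planted to be
          lv[lv == "high"] <- "medium"
          if (tis %in% hot_critical) lv[1] <- "high"
        }
        rows[[tis]] <- data.frame(gene_id = gid, tissue = tis,
                                  cell_type = cts, level = lv,
                                  stringsAsFactors = FALSE)
      }
      normal[[gid]] <- do.call(rbind, rows)
    }

    # --- pathology counts -------------------------------------------------
    if (genes$has_protein_evidence[i]) {
      designated <- if (cls %in% hot_classes) {
        sample(config$tumors, sample(1:3, 1))
      } else {
        character(0)
      }
      lt_all <- cls == "low_score"
      cells <- lapply(config$tumors, function(tt) {
        if (tt %in% designated) {
          x <- draw_counts(config$patients_per_tumor, sim_probs$hot,
                           config$cutoff, "ge")
        } else if (stats::runif(1) < config$missing_cell_rate) {
          x <- c(high = 0L, medium = 0L, low = 0L, not_detected = 0L)
        } else {
          x <- draw_counts(config$patients_per_tumor, sim_probs$background,
                           config$cutoff, if (lt_all) "lt" else "none")
        }
        data.frame(gene_id = gid, gene_symbol = truth$gene_symbol[i],
                   tumor_type = tt, n_high = x[["high"]],
                   n_medium = x[["medium"]], n_low = x[["low"]],
                   n_not_detected = x[["not_detected"]],
                   stringsAsFactors = FALSE)
      })
      pathology[[gid]] <- do.call(rbind, cells)

      # --- FPKM, rank-coupled to the realized scores ---------------------
      if (length(fpkm_tumors) >= 3) {
        pt <- pathology[[gid]]
        pt <- pt[match(fpkm_tumors, pt$tumor_type), , drop = FALSE]
        s <- quasi_h_score(pt$n_high, pt$n_medium, pt$n_low,
                           pt$n_not_detected)
        rho <- if (cls == "fails_rna") 0 else config$rna_concordance
        want <- if (cls %in% concordant_pass) {
          "pass"
        } else if (cls == "fails_rna") "fail" else "any"
        fpkm[[gid]] <- draw_fpkm(gid, fpkm_tumors, s, rho, want)
      }
    }

    # --- surfaceome membership -------------------------------------------
    in_surface <- switch(
      cls,
      non_surface_high = FALSE,
      candidate = , fails_rna = , fails_literature = ,
      fails_membranous = TRUE,
      stats::runif(1) < 0.5
    )
    if (in_surface) surface <- c(surface, gid)
  }

  flags <- data.frame(
    gene_id = truth$gene_id,
    rna_consistent = classes != "fails_rna",
    literature_conform = classes != "fails_literature",
    membranous_staining = classes != "fails_membranous",
    stringsAsFactors = FALSE
  )

  list(
    genes = genes,
    normal = rbind_or_empty(normal, normal_table_proto()),
    pathology = rbind_or_empty(pathology, data.frame(
      gene_id = character(0), gene_symbol = character(0),
      tumor_type = character(0), n_high = integer(0), n_medium = integer(0),
      n_low = integer(0), n_not_detected = integer(0),
      stringsAsFactors = FALSE
    )),
    surfaceome = surface,
    fpkm = rbind_or_empty(fpkm, data.frame(
      gene_id = character(0), tumor_type = character(0), fpkm = numeric(0),
      stringsAsFactors = FALSE
    )),
    flags = flags,
    truth = truth[, c("gene_id", "class")],
    config = config
  )
}

# Gaussian-copula FPKM vector with target rank correlation `rho` to the
# score vector; resampled until the default spearman rule (r >= 0.3,
# >= 5 pairs) returns the planted verdict
draw_fpkm <- function(gid, tumors, scores, rho, want = c("any", "pass",
                                                         "fail")) {
  want <- match.arg(want)
  ok <- !is.na(scores)
  m <- sum(ok)
  zs <- rep(0, length(scores))
  if (m > 0) {
    zs[ok] <- stats::qnorm((rank(scores[ok], ties.method = "average") - 0.5)
                           / m)
  }
  for (i in 1:1000) {
    z <- rho * zs + sqrt(1 - rho^2) * stats::rnorm(length(scores))
    values <- round(5 * exp(0.9 * z), 2)
    verdict <- if (m >= 5 && stats::sd(scores[ok]) > 0 &&
                   stats::sd(values[ok]) > 0) {
      stats::cor(scores[ok], values[ok], method = "spearman") >= 0.3
    } else {
      FALSE  # indeterminate fails the default rule
    }
    if (want == "any" || (want == "pass") == verdict) {
      return(data.frame(gene_id = gid, tumor_type = tumors, fpkm = values,
                        stringsAsFactors = FALSE))
    }
  }
  stop("could not satisfy RNA-concordance constraint for ", gid,
       call. = FALSE)
}

#' Write a simulated dataset to disk in the pipeline's file dialects
#'
#' Writes `genes.xml`, `normal_tissue.tsv`, `pathology.tsv`,
#' `surfaceome.tsv`, `fpkm.tsv`, `flags.tsv` (0/1 flag columns) and
#' `ground_truth.tsv` under `dir`. Deterministic for a given dataset.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gene_table_xml(dataset$genes, dataset$normal, p("genes.xml"))
  write_gene_table_tsv(dataset$genes, dataset$normal,
                       p("normal_tissue.tsv"))
  write_pathology_tsv(dataset$pathology, p("pathology.tsv"))
  write_surfaceome_tsv(dataset$surfaceome, p("surfaceome.tsv"))
  write_fpkm_tsv(dataset$fpkm, p("fpkm.tsv"))
  fl <- dataset$flags
  write_tsv(data.frame(
    gene_id = fl$gene_id,
    rna_consistent = as.integer(fl$rna_consistent),
    literature_conform = as.integer(fl$literature_conform),
    membranous_staining = as.integer(fl$membranous_staining),
    stringsAsFactors = FALSE
  ), p("flags.tsv"))
  write_tsv(dataset$truth, p("ground_truth.tsv"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory holding the files.
#' @return List with the same table components as [simulate_dataset()]
#'   (without `config`).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  gt <- read_membrane_gene_table(p("genes.xml"), format = "xml")
  fl <- utils::read.delim(p("flags.tsv"), stringsAsFactors = FALSE)
  fl$rna_consistent <- fl$rna_consistent == 1
  fl$literature_conform <- fl$literature_conform == 1
  fl$membranous_staining <- fl$membranous_staining == 1
  list(
    genes = gt$genes,
    normal = gt$normal,
    pathology = read_pathology_counts(p("pathology.tsv")),
    surfaceome = read_surfaceome(p("surfaceome.tsv")),
    fpkm = read_fpkm(p("fpkm.tsv")),
    flags = fl,
    truth = utils::read.delim(p("ground_truth.tsv"),
                              stringsAsFactors = FALSE)
  )
}

#' Simulate tissue-microarray core readings
#'
#' Generates per-tumor triples of (intensity, percent-positive) core
#' readings whose per-tumor H-scores are drawn from a normal distribution
#' with the requested mean and SD, clamped to the attainable \[0, 300\]
#' scale. Core-level jitter is mean-centered within each tumor, so the
#' per-tumor H-score (mean of usable cores) equals the drawn per-tumor
#' target exactly; with `sd = 0` every per-tumor H-score equals
#' `mean_hscore`. A fraction `dropout_rate` of cores is flagged as
#' containing no tumor cells.
#'
#' @param n_tumors Number of tumors.
#' @param mean_hscore Target mean per-tumor H-score, in \[0, 300\].
#' @param sd Target between-tumor SD, non-negative.
#' @param cores_per_tumor Cores extracted per tumor; default 3.
#' @param dropout_rate Probability a core contains no tumor cells; default
#'   0.
#' @param seed Integer seed.
#' @return data.frame with `tumor_id`, `core_id`, `intensity`,
#'   `percent_positive`, `has_tumor_cells`.
#' @export
simulate_tma_cores <- function(n_tumors, mean_hscore, sd,
                               cores_per_tumor = 3, dropout_rate = 0,
                               seed = 1) {
  if (mean_hscore < 0 || mean_hscore > 300) {
    stop("mean_hscore must be in [0, 300]", call. = FALSE)
  }
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("dropout_rate must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_tumors), function(i) {
      target <- min(300, max(0, stats::rnorm(1, mean_hscore, sd)))
      jitter <- stats::rnorm(cores_per_tumor, 0, 12)
      jitter <- jitter - mean(jitter)
      while (any(target + jitter < 0 | target + jitter > 300)) {
        jitter <- jitter / 2
        if (max(abs(jitter)) < 1e-9) jitter[] <- 0
      }
      score <- target + jitter
      # express each core score as intensity x percent
      intensity <- ifelse(score == 0, 0L, pmax(1L, ceiling(score / 100)))
      percent <- ifelse(intensity == 0, 0, score / intensity)
      data.frame(
        tumor_id = sprintf("T%03d", i),
        core_id = sprintf("T%03d_c%d", i, seq_len(cores_per_tumor)),
        intensity = as.integer(intensity),
        percent_positive = percent,
        has_tumor_cells = !(stats::runif(cores_per_tumor) < dropout_rate),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
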