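#' RNA-consistency rule configuration
#'
#' The published screen requires concordance between IHC-derived tumor
#' scores and RNA-seq (FPKM) levels but does not quantify it; two explicit
#' rules are provided.
#'
#' @param method `"spearman"` (default): consistent iff the Spearman rank
#'   correlation between the gene's quasi H-scores and FPKM values across
#'   tumor types with both defined is at least `threshold` and at least
#'   `min_pairs` pairs exist. `"support"`: consistent iff FPKM exceeds
#'   `fpkm_floor` in every tumor type where the quasi H-score is at least
#'   `score_cutoff`.
#' @param threshold Minimum Spearman correlation; default 0.3.
#' @param min_pairs Minimum number of (score, FPKM) pairs; default 5.
#' @param fpkm_floor FPKM support floor for the `"support"` rule; default 1.
#' @param score_cutoff Score cutoff for the `"support"` rule; default 150.
#' @param indeterminate What an indeterminate result (too few pairs, or a
#'   degenerate correlation) maps to: `"fail"` (default) or `"pass"`.
#' @return A list of class `rna_rule`.
#' @export
rna_rule <- function(method = c("spearman", "support"), threshold = 0.3,
                     min_pairs = 5, fpkm_floor = 1, score_cutoff = 150,
                     indeterminate = c("fail", "pass")) {
  structure(
    list(method = match.arg(method), threshold = threshold,
         min_pairs = min_pairs, fpkm_floor = fpkm_floor,
         score_cutoff = score_cutoff,
         indeterminate = match.arg(indeterminate)),
    class = "rna_rule"
  )
}

#' IHC--RNA consistency of one gene
#'
#' First validation flag: agreement between the gene's per-tumor quasi
#' H-scores and its per-tumor FPKM values, under a configurable rule
#' (see [rna_rule()]).
#'
#' @param gene_id Gene identifier (must be a row of `score_matrix`).
#' @param score_matrix Quasi H-score matrix ([quasi_h_matrix()]).
#' @param fpkm FPKM table (`gene_id`, `tumor_type`, `fpkm`).
#' @param rule An [rna_rule()].
#' @return One-row data.frame: `gene_id`, `r` (statistic, `NA` when
#'   indeterminate), `n_pairs`, `status`
#'   (`"ok"`/`"too_few_pairs"`/`"degenerate"`), `consistent` (logical).
#' @export
rna_consistency <- function(gene_id, score_matrix, fpkm, rule = rna_rule()) {
  if (!gene_id %in% rownames(score_matrix)) {
    stop("gene ", sQuote(gene_id), " absent from the score matrix",
         call. = FALSE)
  }
  scores <- score_matrix[gene_id, ]
  fp <- fpkm[fpkm$gene_id == gene_id, , drop = FALSE]
  fpv <- fp$fpkm[match(names(scores), fp$tumor_type)]
  ok <- !is.na(scores) & !is.na(fpv)
  s <- scores[ok]
  f <- fpv[ok]
  n <- length(s)
  res <- function(r, status, consistent) {
    data.frame(gene_id = gene_id, r = r, n_pairs = n, status = status,
               consistent = consistent, stringsAsFactors = FALSE)
  }
  indeterminate_pass <- rule$indeterminate == "pass"
  if (rule$method == "support") {
    hot <- !is.na(scores) & scores >= rule$score_cutoff
    fphot <- fpv[hot]
    if (any(is.na(fphot))) {
      return(res(NA_real_, "too_few_pairs", indeterminate_pass))
    }
    return(res(NA_real_, "ok", all(fphot > rule$fpkm_floor)))
  }
  if (n < rule$min_pairs) {
    return(res(NA_real_, "too_few_pairs", indeterminate_pass))
  }
  if (stats::sd(s) == 0 || stats::sd(f) == 0) {
    return(res(NA_real_, "degenerate", indeterminate_pass))
  }
  r <- stats::cor(s, f, method = "spearman")
  res(r, "ok", r >= rule$threshold)
}

#' Apply the three-flag validation to the potential target set
#'
#' A potential target is a candidate iff it is RNA-consistent, conforms to
#' the literature, and shows predominant membranous staining. The latter
#' two verdicts are curated inputs (manual literature review and IHC image
#' inspection), never computed.
#'
#' @param potential Character vector of potential target gene ids.
#' @param flags data.frame with `gene_id`, `literature_conform`,
#'   `membranous_staining` (logical or 0/1).
#' @param rna_results data.frame from rbind-ing [rna_consistency()] rows,
#'   covering every potential target.
#' @return data.frame with `gene_id`, the three logical flags and
#'   `is_candidate` (their conjunction), one row per potential target in
#'   input order.
#' @export
apply_validation <- function(potential, flags, rna_results) {
  miss <- setdiff(potential, intersect(flags$gene_id, rna_results$gene_id))
  if (length(miss) > 0) {
    stop("missing validation flags for potential target(s): ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  fl <- flags[match(potential, flags$gene_id), , drop = FALSE]
  rna <- rna_results[match(potential, rna_results$gene_id), , drop = FALSE]
  out <- data.frame(
    gene_id = potential,
    rna_consistent = as.logical(rna$consistent),
    literature_conform = as.logical(fl$literature_conform),
    membranous_staining = as.logical(fl$membranous_staining),
    stringsAsFactors = FALSE
  )
  out$is_candidate <- out$rna_consistent & out$literature_conform &
    out$membranous_staining
  out
}

#' Prioritization profile of one gene
#'
#' Summaries used to rank candidate targets: the maximum quasi H-score over
#' tumor types, the number of tumor types at or above the cutoff, and the
#' normal-tissue burden (tissues at high or medium, and at high, after
#' taking the maximum level over cell types within each tissue).
#'
#' @param gene_id Gene identifier.
#' @param score_matrix Quasi H-score matrix.
#' @param normal Long normal-tissue table.
#' @param cutoff Tumor-score cutoff; default 150.
#' @return One-row data.frame: `gene_id`, `max_quasi_h`,
#'   `n_tumors_ge_cutoff`, `n_normal_high_or_medium`, `n_normal_high`.
#' @export
priority_profile <- function(gene_id, score_matrix, normal, cutoff = 150) {
  scores <- if (gene_id %in% rownames(score_matrix)) {
    score_matrix[gene_id, ]
  } else {
    NA_real_
  }
  max_q <- if (all(is.na(scores))) NA_real_ else max(scores, na.rm = TRUE)
  n_ge <- sum(!is.na(scores) & scores >= cutoff)
  prof <- normal[normal$gene_id == gene_id, , drop = FALSE]
  w <- ihc_level_weights()[prof$level]
  tis_max <- if (nrow(prof) > 0) {
    tapply(w, prof$tissue, max)
  } else {
    numeric(0)
  }
  data.frame(
    gene_id = gene_id,
    max_quasi_h = max_q,
    n_tumors_ge_cutoff = n_ge,
    n_normal_high_or_medium = sum(tis_max >= 2),
    n_normal_high = sum(tis_max >= 3),
    stringsAsFactors = FALSE
  )
}

#' Rank candidate targets
#'
#' Total, deterministic order: maximum quasi H-score (descending), number
#' of tumor types at or above the cutoff (descending), normal-tissue
#' high/medium burden (ascending), gene id (ascending, as the final
#' tie-break).
#'
#' @param profiles data.frame of [priority_profile()] rows.
#' @return The same data.frame, reordered.
#' @export
rank_candidates <- function(profiles) {
  key <- profiles$max_quasi_h
  key[is.na(key)] <- -Inf
  profiles[order(-key, -profiles$n_tumors_ge_cutoff,
                 profiles$n_normal_high_or_medium, profiles$gene_id), ,
           drop = FALSE]
}

#' Run screening plus validation end to end
#'
#' Convenience wrapper: [run_screening()], then [rna_consistency()] for
#' every potential target, [apply_validation()], and ranked
#' [priority_profile()]s for the candidates.
#'
#' @inheritParams run_screening
#' @param rule RNA-consistency rule; default [rna_rule()].
#' @return List with `screening` (the [run_screening()] result),
#'   `validation` (the [apply_validation()] table), `candidates` (character
#'   vector of validated gene ids) and `priorities` (ranked profile table
#'   for the candidates).
#' @export
run_pipeline <- function(dataset, cutoff = 150,
                         critical = critical_tissues(), rule = rna_rule()) {
  scr <- run_screening(dataset, cutoff = cutoff, critical = critical)
  rna <- do.call(rbind, lapply(scr$potential, rna_consistency,
                               score_matrix = scr$scores,
                               fpkm = dataset$fpkm, rule = rule))
  if (is.null(rna)) {
    rna <- data.frame(gene_id = character(0), r = numeric(0),
                      n_pairs = integer(0), status = character(0),
                      consistent = logical(0), stringsAsFactors = FALSE)
  }
  val <- apply_validation(scr$potential, dataset$flags, rna)
  candidates <- val$gene_id[val$is_candidate]
  prio <- do.call(rbind, lapply(candidates, priority_profile,
                                score_matrix = scr$scores,
                                normal = dataset$normal, cutoff = cutoff))
  if (!is.null(prio)) prio <- rank_candidates(prio)
  list(screening = scr, validation = val, candidates = candidates,
       priorities = prio, rna = rna)
}
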