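#' H-score of one tissue core
#'
#' Semiquantitative IHC score in \[0, 300\]: staining intensity (0 not
#' detected, 1 low, 2 moderate, 3 high) multiplied by the percentage of
#' positive cells. Vectorized over cores.
#'
#' @param intensity Integer staining intensity in {0, 1, 2, 3}.
#' @param percent_positive Percent positive cells in \[0, 100\].
#' @return Numeric score(s) in \[0, 300\].
#' @seealso [core_h_score_strata()] for the stratified (sum over
#'   intensities) form.
#' @export
core_h_score <- function(intensity, percent_positive) {
  if (any(!intensity %in% 0:3)) {
    stop("intensity must be an integer in 0..3", call. = FALSE)
  }
  if (any(percent_positive < 0 | percent_positive > 100)) {
    stop("percent_positive must be in [0, 100]", call. = FALSE)
  }
  intensity * percent_positive
}

#' Stratified H-score of one core
#'
#' General H-score form: the sum over intensity strata of intensity times
#' the percentage of cells at that intensity; the percentages must sum to
#' at most 100. The single-intensity product form ([core_h_score()]) is the
#' default reading used throughout the pipeline.
#'
#' @param intensity Integer vector of intensities in {0, 1, 2, 3}.
#' @param percent_positive Percent of cells at each intensity; sums to
#'   <= 100.
#' @return A single score in \[0, 300\].
#' @export
core_h_score_strata <- function(intensity, percent_positive) {
  if (any(!intensity %in% 0:3)) {
    stop("intensity must be integers in 0..3", call. = FALSE)
  }
  if (any(percent_positive < 0) || sum(percent_positive) > 100 + 1e-9) {
    stop("stratum percentages must be non-negative and sum to <= 100",
         call. = FALSE)
  }
  sum(intensity * percent_positive)
}

#' Per-tumor H-score from its tissue cores
#'
#' Arithmetic mean of the usable cores of one tumor (typically three).
#' Cores containing no tumor cells are excluded; a tumor whose cores are
#' all excluded yields no score (`NA` with `n_cores_used` 0), signalling
#' exclusion from analysis rather than a zero.
#'
#' @param cores data.frame with columns `intensity`, `percent_positive`,
#'   `has_tumor_cells` (logical) — the readings of one tumor.
#' @return One-row data.frame: `h_score`, `n_cores_used`.
#' @export
tumor_h_score <- function(cores) {
  usable <- cores[cores$has_tumor_cells, , drop = FALSE]
  if (nrow(usable) == 0) {
    return(data.frame(h_score = NA_real_, n_cores_used = 0L))
  }
  sc <- core_h_score(usable$intensity, usable$percent_positive)
  data.frame(h_score = mean(sc), n_cores_used = nrow(usable))
}

#' Per-tumor H-scores for a whole TMA reading table
#'
#' @param readings data.frame with `tumor_id`, `intensity`,
#'   `percent_positive`, `has_tumor_cells`.
#' @return data.frame with `tumor_id`, `h_score`, `n_cores_used`; tumors
#'   with no usable core carry `NA` scores.
#' @export
tma_h_scores <- function(readings) {
  ids <- unique(readings$tumor_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    tumor_h_score(readings[readings$tumor_id == id, , drop = FALSE])
  }))
  cbind(data.frame(tumor_id = ids, stringsAsFactors = FALSE), out)
}

#' One-sample t-test from summary statistics
#'
#' Tests whether the mean of a sample (given as mean, SD with the n-1
#' denominator, and n) differs from a reference value `mu0` — here, whether
#' experimentally measured mean H-scores differ from the cohort-derived
#' quasi H-score. Two-sided, with a 95 percent confidence interval for the
#' mean difference.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (n-1 denominator), non-negative.
#' @param n Sample size, at least 2.
#' @param mu0 Reference value.
#' @param conf_level Confidence level; default 0.95.
#' @return One-row data.frame: `mean_difference`, `ci_low`, `ci_high`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
one_sample_t <- function(mean, sd, n, mu0, conf_level = 0.95) {
  stopifnot(length(mean) == 1, length(sd) == 1, length(n) == 1)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  diff <- mean - mu0
  df <- n - 1
  if (sd == 0) {
    if (diff != 0) {
      stop("degenerate test: zero sample variance with mean != mu0",
           call. = FALSE)
    }
    return(data.frame(mean_difference = 0, ci_low = 0, ci_high = 0,
                      t_statistic = 0, df = df, p_value = 1))
  }
  se <- sd / sqrt(n)
  t <- diff / se
  half <- stats::qt(1 - (1 - conf_level) / 2, df) * se
  data.frame(
    mean_difference = diff, ci_low = diff - half, ci_high = diff + half,
    t_statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df)
  )
}

#' One-sample t-test from raw scores
#'
#' Identical to [one_sample_t()] applied to the sample mean and SD of
#' `scores`.
#'
#' @param scores Numeric vector of at least 2 values (e.g. per-tumor
#'   H-scores).
#' @inheritParams one_sample_t
#' @return See [one_sample_t()].
#' @export
one_sample_t_raw <- function(scores, mu0, conf_level = 0.95) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) {
    stop("need at least 2 scores", call. = FALSE)
  }
  one_sample_t(mean(scores), stats::sd(scores), length(scores), mu0,
               conf_level)
}

#' Pearson correlation of tumor scores with FPKM across genes
#'
#' For one tumor type: pairs per-gene scores (quasi or measured H-scores)
#' with per-gene FPKM values by gene id, drops incomplete pairs, and
#' returns the Pearson correlation with its two-sided p-value (t
#' approximation on n-2 degrees of freedom).
#'
#' @param scores Named numeric vector of per-gene scores.
#' @param fpkm Named numeric vector of per-gene FPKM values.
#' @return One-row data.frame: `r`, `p_value`, `n_pairs`, `status`
#'   (`"ok"` or `"degenerate"` when either paired vector is constant, in
#'   which case `r` and `p_value` are `NA`).
#' @export
score_fpkm_correlation <- function(scores, fpkm) {
  common <- intersect(names(scores), names(fpkm))
  s <- scores[common]
  f <- fpkm[common]
  ok <- !is.na(s) & !is.na(f)
  s <- s[ok]
  f <- f[ok]
  n <- length(s)
  if (n < 3) {
    stop("need at least 3 complete (score, FPKM) pairs; got ", n,
         call. = FALSE)
  }
  if (stats::sd(s) == 0 || stats::sd(f) == 0) {
    return(data.frame(r = NA_real_, p_value = NA_real_, n_pairs = n,
                      status = "degenerate", stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(s, f, method = "pearson")
  data.frame(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = n,
             status = "ok", stringsAsFactors = FALSE)
}
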