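#' Ordinal IHC expression levels
#'
#' Immunohistochemistry expression is scored on a four-level ordinal scale:
#' not detected < low < medium < high, with fixed numeric weights 0, 1, 2, 3.
#' The same scale parameterizes both the normal-tissue annotation and the
#' per-tumor patient counts feeding the quasi H-score.
#'
#' @return Character vector of the four canonical level names, in increasing
#'   order of expression.
#' @export
ihc_levels <- function() {
  c("not_detected", "low", "medium", "high")
}

#' Numeric weights of the ordinal IHC levels
#'
#' @return Named numeric vector mapping each level to its weight
#'   (`not_detected` = 0, `low` = 1, `medium` = 2, `high` = 3).
#' @export
ihc_level_weights <- function() {
  c(not_detected = 0, low = 1, medium = 2, high = 3)
}

#' Parse IHC level tokens
#'
#' Accepts the tokens used across HPA-style exports, case-insensitively:
#' `"Not detected"`, `"Low"`, `"Medium"`, `"Moderate"` and `"High"`.
#' `"Moderate"` is the staining-intensity synonym of `"Medium"` and maps to
#' `medium`.
#'
#' @param x Character vector of level tokens.
#' @param context Optional string (e.g. a gene id) prepended to the error
#'   message when an unknown token is met.
#' @return Character vector of canonical level names (see [ihc_levels()]).
#' @export
parse_ihc_level <- function(x, context = NULL) {
  key <- gsub("[ _]+", " ", trimws(tolower(as.character(x))))
  map <- c(
    "not detected" = "not_detected",
    "low" = "low",
    "medium" = "medium",
    "moderate" = "medium",
    "high" = "high"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    where <- if (is.null(context)) "" else paste0(" for ", context)
    stop("unknown IHC level token(s)", where, ": ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  out
}

#' Default tumor-type vocabulary
#'
#' The 20 tumor types covered by the HPA pathology data.
#'
#' @return Character vector of 20 tumor-type names.
#' @export
tumor_types <- function() {
  c(
    "breast cancer", "carcinoid", "cervical cancer", "colorectal cancer",
    "endometrial cancer", "glioma", "head and neck cancer", "liver cancer",
    "lung cancer", "lymphoma", "melanoma", "ovarian cancer",
    "pancreatic cancer", "prostate cancer", "renal cancer", "skin cancer",
    "stomach cancer", "testis cancer", "thyroid cancer", "urothelial cancer"
  )
}

#' Tumor types with transcriptome (FPKM) data
#'
#' The 17 tumor types for which per-tumor FPKM summaries are available
#' (TCGA cohorts); carcinoid, lymphoma and skin cancer lack them.
#'
#' @return Character vector of 17 tumor-type names.
#' @export
fpkm_tumor_types <- function() {
  setdiff(tumor_types(), c("carcinoid", "lymphoma", "skin cancer"))
}

#' Default normal-tissue vocabulary
#'
#' The 45 normal tissues of the HPA normal-tissue IHC atlas.
#'
#' @return Character vector of 45 tissue names.
#' @export
normal_tissues <- function() {
  c(
    "adipose tissue", "adrenal gland", "appendix", "bone marrow", "breast",
    "bronchus", "caudate", "cerebellum", "cerebral cortex", "cervix, uterine",
    "colon", "duodenum", "endometrium", "epididymis", "esophagus",
    "fallopian tube", "gallbladder", "heart muscle", "hippocampus", "kidney",
    "liver", "lung", "lymph node", "nasopharynx", "oral mucosa", "ovary",
    "pancreas", "parathyroid gland", "placenta", "prostate", "rectum",
    "salivary gland", "seminal vesicle", "skeletal muscle", "skin",
    "small intestine", "smooth muscle", "soft tissue", "spleen", "stomach",
    "testis", "thyroid gland", "tonsil", "urinary bladder", "vagina"
  )
}

#' Critical normal tissues for on-target off-tumor toxicity
#'
#' The 13 normal tissues in which high target expression disqualifies a gene
#' from ADC-target consideration: lung, the seven gastrointestinal
#' sub-tissues (oral mucosa, esophagus, stomach, duodenum, small intestine,
#' colon, rectum), liver, kidney, heart muscle, skin and bone marrow.
#'
#' @return Character vector of 13 tissue names, a subset of
#'   [normal_tissues()].
#' @export
critical_tissues <- function() {
  c(
    "lung", "oral mucosa", "esophagus", "stomach", "duodenum",
    "small intestine", "colon", "rectum", "liver", "kidney",
    "heart muscle", "skin", "bone marrow"
  )
}

# internal: assert tissue names belong to the 45-tissue vocabulary
check_tissue_names <- function(tissues) {
  unknown <- setdiff(unique(tissues), normal_tissues())
  if (length(unknown) > 0) {
    stop("unknown normal tissue name(s): ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
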