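# small in-code fixtures shared across test files

# brute-force quasi H-score oracle: lay out the individual patients and
# average their ordinal weights
oracle_quasi_h <- function(n_high, n_medium, n_low, n_not_detected) {
  w <- rep(c(3, 2, 1, 0), c(n_high, n_medium, n_low, n_not_detected))
  if (length(w) == 0) return(NA_real_)
  mean(w) * 100
}

# every non-negative integer 4-vector (high, medium, low, nd) with total <= tmax
all_count_vectors <- function(tmax) {
  grid <- expand.grid(n_high = 0:tmax, n_medium = 0:tmax, n_low = 0:tmax,
                      n_not_detected = 0:tmax)
  grid[rowSums(grid) <= tmax, , drop = FALSE]
}

# three-gene XML gene-table fixture; gene B lacks a tissue-expression block,
# gene C is outside the membrane class
write_three_gene_xml <- function(path, level_b = "Low") {
  genes <- data.frame(
    gene_id = c("ENSG_A", "ENSG_B", "ENSG_C"),
    gene_symbol = c("GENEA", "GENEB", "GENEC"),
    is_membrane = c(TRUE, TRUE, FALSE),
    has_protein_evidence = c(TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  normal <- data.frame(
    gene_id = c("ENSG_A", "ENSG_A", "ENSG_C"),
    tissue = c("lung", "colon", "skin"),
    cell_type = c("macrophages", "glandular cells", "epidermal cells"),
    level = c("high", "medium", "low"),
    stringsAsFactors = FALSE
  )
  write_gene_table_xml(genes, normal, path)
  if (level_b != "Low") {
    # inject a raw (possibly invalid) level token for parser error tests
    txt <- readLines(path)
    txt <- sub(">High<", paste0(">", level_b, "<"), txt, fixed = TRUE)
    writeLines(txt, path)
  }
  path
}

# minimal coherent dataset for screening tests: one hand-built gene per role
tiny_dataset <- function() {
  genes <- data.frame(
    gene_id = c("G_CAND", "G_NOMEM", "G_NOEV", "G_CRIT", "G_LOW",
                "G_NOSURF"),
    gene_symbol = paste0("S", 1:6),
    is_membrane = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    has_protein_evidence = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  normal <- data.frame(
    gene_id = c("G_CAND", "G_CRIT", "G_LOW", "G_NOSURF", "G_NOMEM"),
    tissue = c("cerebral cortex", "stomach", "lung", "testis", "lung"),
    cell_type = "glandular cells",
    level = c("high", "high", "medium", "low", "high"),
    stringsAsFactors = FALSE
  )
  pathology <- data.frame(
    gene_id = c("G_CAND", "G_LOW", "G_NOSURF", "G_CRIT"),
    gene_symbol = c("S1", "S5", "S6", "S4"),
    tumor_type = "lymphoma",
    n_high = c(8L, 1L, 10L, 12L),
    n_medium = c(2L, 2L, 1L, 0L),
    n_low = c(1L, 3L, 1L, 0L),
    n_not_detected = c(1L, 6L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  fpkm <- data.frame(
    gene_id = rep(c("G_CAND", "G_NOSURF"), each = 6),
    tumor_type = rep(fpkm_tumor_types()[1:6], 2),
    fpkm = c(1:6, 6:1),
    stringsAsFactors = FALSE
  )
  flags <- data.frame(
    gene_id = genes$gene_id,
    rna_consistent = TRUE, literature_conform = TRUE,
    membranous_staining = TRUE, stringsAsFactors = FALSE
  )
  list(genes = genes, normal = normal, pathology = pathology,
       surfaceome = c("G_CAND", "G_CRIT", "G_LOW"), fpkm = fpkm,
       flags = flags)
}
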