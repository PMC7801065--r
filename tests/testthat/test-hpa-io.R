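test_that("XML gene table parses records, evidence flags and profiles", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_three_gene_xml(path)
  out <- read_membrane_gene_table(path)
  expect_equal(nrow(out$genes), 3)
  expect_equal(sum(!out$genes$has_protein_evidence), 1)
  expect_equal(out$genes$gene_id[!out$genes$has_protein_evidence], "ENSG_B")
  expect_equal(out$genes$is_membrane,
               c(TRUE, TRUE, FALSE)[match(out$genes$gene_id,
                                          c("ENSG_A", "ENSG_B", "ENSG_C"))])
  prof_a <- out$normal[out$normal$gene_id == "ENSG_A", ]
  expect_setequal(prof_a$tissue, c("lung", "colon"))
  expect_setequal(prof_a$level, c("high", "medium"))
})

test_that("empty gene list parses to empty tables without error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<?xml version=\"1.0\"?>", "<proteinAtlas>",
               "</proteinAtlas>"), path)
  out <- read_membrane_gene_table(path)
  expect_equal(nrow(out$genes), 0)
  expect_equal(nrow(out$normal), 0)
})

test_that("unknown level tokens raise a parse error naming gene and token", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_three_gene_xml(path, level_b = "Ascending")
  expect_error(read_membrane_gene_table(path), "Ascending")
  expect_error(read_membrane_gene_table(path), "ENSG_A")
})

test_that("Moderate maps to medium, case-insensitively", {
  expect_equal(parse_ihc_level(c("Moderate", "MEDIUM", "not Detected")),
               c("medium", "medium", "not_detected"))
})

test_that("duplicate gene ids are a validation error", {
  path <- withr::local_tempfile(fileext = ".xml")
  genes <- data.frame(gene_id = c("ENSG_A", "ENSG_A"),
                      gene_symbol = c("X", "X"), is_membrane = TRUE,
                      has_protein_evidence = FALSE)
  empty_normal <- data.frame(gene_id = character(0), tissue = character(0),
                             cell_type = character(0), level = character(0))
  write_gene_table_xml(genes, empty_normal, path)
  expect_error(read_membrane_gene_table(path), "duplicate gene_id")
})

test_that("tissue-TSV dialect round-trips, incl. evidence-less genes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  genes <- data.frame(
    gene_id = c("ENSG_A", "ENSG_B"), gene_symbol = c("GA", "GB"),
    is_membrane = TRUE, has_protein_evidence = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  normal <- data.frame(gene_id = "ENSG_A", tissue = "lung",
                       cell_type = "macrophages", level = "medium",
                       stringsAsFactors = FALSE)
  write_gene_table_tsv(genes, normal, path)
  out <- read_membrane_gene_table(path, format = "tsv")
  expect_equal(out$genes, genes, ignore_attr = TRUE)
  expect_equal(out$normal, normal, ignore_attr = TRUE)
})

test_that("pathology counts parse, blanks read as zero, rows preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Gene\tGene name\tCancer\tHigh\tMedium\tLow\tNot detected",
    "ENSG_1\tGENE1\tlymphoma\t11\t1\t0\t0",
    "ENSG_1\tGENE1\tglioma\t\t\t\t",
    "ENSG_2\tGENE2\tlymphoma\t2\t3\t4\t1"
  ), path)
  out <- read_pathology_counts(path)
  expect_equal(nrow(out), 3)
  r1 <- out[out$gene_id == "ENSG_1" & out$tumor_type == "lymphoma", ]
  expect_equal(r1$n_high + r1$n_medium + r1$n_low + r1$n_not_detected, 12L)
  blank <- out[out$tumor_type == "glioma", ]
  expect_equal(unlist(blank[, c("n_high", "n_medium", "n_low",
                                "n_not_detected")], use.names = FALSE),
               rep(0L, 4))
})

test_that("pathology parser rejects negative and malformed counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tGene name\tCancer\tHigh\tMedium\tLow\tNot detected",
               "ENSG_1\tG1\tglioma\t-1\t0\t0\t0"), path)
  expect_error(read_pathology_counts(path), "negative.*row\\(s\\) 1")
  writeLines(c("Gene\tGene name\tCancer\tHigh\tMedium\tLow\tNot detected",
               "ENSG_1\tG1\tglioma\tmany\t0\t0\t0"), path)
  expect_error(read_pathology_counts(path), "malformed")
})

test_that("a full gene x tumor pathology grid yields one record per row", {
  d <- simulate_dataset(sim_config(
    n_genes_per_class = c(candidate = 2), seed = 11,
    missing_cell_rate = 0
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathology_tsv(d$pathology, path)
  out <- read_pathology_counts(path)
  expect_equal(nrow(out), 2 * 20)
  expect_equal(out, d$pathology, ignore_attr = TRUE)
})

test_that("surfaceome reader deduplicates and handles empty tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tSource", "ENSG_1\tx", "ENSG_2\tx", "ENSG_2\ty",
               "ENSG_3\tx", "ENSG_4\tx"), path)
  expect_setequal(read_surfaceome(path),
                  c("ENSG_1", "ENSG_2", "ENSG_3", "ENSG_4"))
  writeLines("Gene", path)
  expect_length(read_surfaceome(path), 0)
})

test_that("symbol-keyed surfaceome resolves via the id map, drops the rest", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GeneName", "GA", "GB", "NOPE"), path)
  id_map <- data.frame(gene_id = c("ENSG_A", "ENSG_B"),
                       gene_symbol = c("GA", "GB"))
  expect_message(out <- read_surfaceome(path, id_map = id_map),
                 "unresolved")
  expect_setequal(out, c("ENSG_A", "ENSG_B"))
})

test_that("surfaceome table without an identifier column is a schema error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Foo\tBar", "a\tb"), path)
  expect_error(read_surfaceome(path), "identifier column")
})

test_that("FPKM reader keeps absent pairs absent and rejects negatives", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Gene\tCancer\tFPKM", "ENSG_1\tglioma\t2.5",
               "ENSG_1\tmelanoma\t0"), path)
  out <- read_fpkm(path)
  expect_equal(nrow(out), 2)
  expect_false(any(out$tumor_type == "lymphoma"))
  writeLines(c("Gene\tCancer\tFPKM", "ENSG_1\tglioma\t-1"), path)
  expect_error(read_fpkm(path), "negative FPKM")
})

test_that("a simulated dataset round-trips through disk identically", {
  d <- simulate_dataset(sim_config(seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  rd <- read_dataset(dir)
  expect_equal(rd$genes, d$genes, ignore_attr = TRUE)
  expect_equal(rd$pathology, d$pathology, ignore_attr = TRUE)
  expect_equal(rd$fpkm, d$fpkm, ignore_attr = TRUE)
  expect_equal(rd$flags, d$flags, ignore_attr = TRUE)
  expect_setequal(rd$surfaceome, d$surfaceome)
  ord <- function(x) x[order(x$gene_id, x$tissue, x$cell_type), ]
  expect_equal(ord(rd$normal), ord(d$normal), ignore_attr = TRUE)
})
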