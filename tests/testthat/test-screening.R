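test_that("quasi H-score matches direct arithmetic on known cohorts", {
  expect_equal(quasi_h_score(12, 0, 0, 0), 300)
  expect_equal(quasi_h_score(0, 0, 0, 10), 0)
  # 50% low + 30% medium + 20% high = 50 + 60 + 60
  expect_equal(quasi_h_score(2, 3, 5, 0), 170)
  expect_true(is.na(quasi_h_score(0, 0, 0, 0)))
  expect_error(quasi_h_score(-1, 0, 0, 2), "negative")
})

test_that("quasi H-score equals the patient-enumeration oracle for T <= 8", {
  grid <- all_count_vectors(8)
  got <- quasi_h_score(grid$n_high, grid$n_medium, grid$n_low,
                       grid$n_not_detected)
  want <- mapply(oracle_quasi_h, grid$n_high, grid$n_medium, grid$n_low,
                 grid$n_not_detected)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("score boundaries are hit only at uniform-high / none-detected", {
  grid <- all_count_vectors(8)
  grid <- grid[rowSums(grid) > 0, ]
  s <- quasi_h_score(grid$n_high, grid$n_medium, grid$n_low,
                     grid$n_not_detected)
  expect_true(all(s >= 0 & s <= 300))
  all_high <- grid$n_high == rowSums(grid)
  none_above_nd <- grid$n_high + grid$n_medium + grid$n_low == 0
  expect_equal(s == 300, all_high, ignore_attr = TRUE)
  expect_equal(s == 0, none_above_nd, ignore_attr = TRUE)
})

test_that("moving a patient up a category never decreases the score", {
  grid <- all_count_vectors(8)
  grid <- grid[rowSums(grid) > 0, ]
  cols <- c("n_not_detected", "n_low", "n_medium", "n_high")  # ascending
  base <- quasi_h_score(grid$n_high, grid$n_medium, grid$n_low,
                        grid$n_not_detected)
  for (from in 1:3) {
    for (to in (from + 1):4) {
      movable <- grid[[cols[from]]] > 0
      g2 <- grid[movable, ]
      g2[[cols[from]]] <- g2[[cols[from]]] - 1L
      g2[[cols[to]]] <- g2[[cols[to]]] + 1L
      moved <- quasi_h_score(g2$n_high, g2$n_medium, g2$n_low,
                             g2$n_not_detected)
      expect_true(all(moved >= base[movable] - 1e-12),
                  info = sprintf("move %s -> %s", cols[from], cols[to]))
    }
  }
})

test_that("protein-evidence filter partitions exhaustively and disjointly", {
  genes <- tiny_dataset()$genes
  out <- filter_protein_evidence(genes)
  expect_equal(nrow(out$retained) + nrow(out$excluded), nrow(genes))
  expect_length(intersect(out$retained$gene_id, out$excluded$gene_id), 0)
  expect_equal(out$excluded$gene_id, "G_NOEV")

  all_ev <- genes[genes$has_protein_evidence, ]
  expect_equal(nrow(filter_protein_evidence(all_ev)$excluded), 0)
  empty <- genes[0, ]
  out0 <- filter_protein_evidence(empty)
  expect_equal(nrow(out0$retained), 0)
  expect_equal(nrow(out0$excluded), 0)
})

test_that("critical-tissue exclusion triggers on high only, at tissue max", {
  normal <- data.frame(
    gene_id = c("g1", "g1", rep("g2", 13), "g3"),
    tissue = c("stomach", "colon", critical_tissues(), "cerebral cortex"),
    cell_type = "glandular cells",
    level = c("high", "low", rep("medium", 13), "high"),
    stringsAsFactors = FALSE
  )
  out <- filter_critical_normal(c("g1", "g2", "g3"), normal)
  expect_equal(out$excluded, "g1")          # high in one stomach cell type
  expect_true("g2" %in% out$retained)       # medium everywhere never excludes
  expect_true("g3" %in% out$retained)       # high only in non-critical tissue
})

test_that("aggregation over cell types within a tissue is the maximum", {
  normal <- data.frame(
    gene_id = "g1", tissue = "liver",
    cell_type = c("hepatocytes", "endothelial cells"),
    level = c("low", "high"), stringsAsFactors = FALSE
  )
  expect_equal(filter_critical_normal("g1", normal)$excluded, "g1")
})

test_that("unknown tissue names are a validation error naming the tissue", {
  normal <- data.frame(gene_id = "g1", tissue = "flux capacitor",
                       cell_type = "x", level = "low")
  expect_error(filter_critical_normal("g1", normal), "flux capacitor")
})

test_that("threshold filter is inclusive at the cutoff, NA never passes", {
  mat <- rbind(
    boundary = c(120, 150, NA),
    under = c(149.9, 149.9, 149.9),
    undefined = c(NA, NA, NA)
  )
  colnames(mat) <- c("glioma", "lymphoma", "melanoma")
  out <- threshold_filter(mat, cutoff = 150)
  expect_equal(out$retained, "boundary")
  expect_equal(unname(out$max_score["boundary"]), 150)
  expect_equal(unname(out$n_ge_cutoff["boundary"]), 1)
  expect_true(is.na(out$max_score["undefined"]))
})

test_that("surfaceome filter is plain set intersection / difference", {
  out <- surfaceome_filter(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(out$retained, c("B", "C"))
  expect_setequal(out$excluded, "A")
  expect_length(surfaceome_filter(c("A", "B"), character(0))$retained, 0)
  expect_length(surfaceome_filter(c("B", "C"), c("B", "C"))$excluded, 0)
})

test_that("run_screening composes the stages with a telescoping audit", {
  d <- tiny_dataset()
  res <- run_screening(d)
  expect_equal(res$audit$stage,
               c("membrane_class", "protein_evidence", "critical_normal",
                 "quasi_h_threshold", "surfaceome"))
  expect_equal(res$audit$n_in[-1], res$audit$n_out[-nrow(res$audit)])
  expect_true(all(res$audit$n_out <= res$audit$n_in))
  expect_equal(res$potential, "G_CAND")
  es <- exit_stages(res$audit)
  expect_equal(unname(es[c("G_NOMEM", "G_NOEV", "G_CRIT", "G_LOW",
                           "G_NOSURF")]),
               c("membrane_class", "protein_evidence", "critical_normal",
                 "quasi_h_threshold", "surfaceome"))
})

test_that("screening output is invariant to input row order", {
  d <- tiny_dataset()
  res1 <- run_screening(d)
  d2 <- d
  perm <- c(4, 2, 6, 1, 3, 5)
  d2$genes <- d2$genes[perm, ]
  d2$pathology <- d2$pathology[rev(seq_len(nrow(d2$pathology))), ]
  d2$normal <- d2$normal[rev(seq_len(nrow(d2$normal))), ]
  res2 <- run_screening(d2)
  expect_equal(res1$potential, res2$potential)
  expect_equal(res1$audit, res2$audit, ignore_attr = TRUE)
})

test_that("a dataset of only non-membrane genes exits fully at stage one", {
  d <- tiny_dataset()
  d$genes <- d$genes[d$genes$gene_id == "G_NOMEM", ]
  d$pathology <- d$pathology[0, ]
  d$normal <- d$normal[d$normal$gene_id == "G_NOMEM", ]
  res <- run_screening(d)
  expect_length(res$potential, 0)
  expect_equal(res$audit$n_out[1], 0)
  expect_equal(res$audit$excluded[1], "G_NOMEM")
})

test_that("a single passing gene survives every stage of the audit", {
  d <- tiny_dataset()
  keep <- "G_CAND"
  d$genes <- d$genes[d$genes$gene_id == keep, ]
  d$pathology <- d$pathology[d$pathology$gene_id == keep, ]
  d$normal <- d$normal[d$normal$gene_id == keep, ]
  res <- run_screening(d)
  expect_equal(res$audit$n_out, rep(1L, 5))
  expect_equal(res$potential, keep)
})

test_that("pathology rows referencing unknown genes are rejected", {
  d <- tiny_dataset()
  d$pathology$gene_id[1] <- "G_GHOST"
  expect_error(run_screening(d), "G_GHOST")
})
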