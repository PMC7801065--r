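#!/usr/bin/env Rscript
# Step 2 — run the screening funnel.
#
# Five ordered stages: membrane class -> protein-level evidence ->
# exclusion of genes with high IHC expression in any of the 13 critical
# normal tissues -> quasi H-score >= 150 in at least one tumor type ->
# intersection with the predicted surfaceome. Writes the per-stage audit,
# the quasi H-score matrix and the potential-target table.

library(adcmine)

dataset <- read_dataset("results/dataset")
scr <- run_screening(dataset)

dir.create("results/screening", showWarnings = FALSE, recursive = TRUE)
write_audit_tsv(scr$audit, "results/screening/audit.tsv")
write_matrix_tsv(round(scr$scores, 1), "results/screening/quasi_h_scores.tsv")

th <- threshold_filter(scr$scores)
pot <- data.frame(
  gene_id = scr$potential,
  gene_symbol = dataset$genes$gene_symbol[
    match(scr$potential, dataset$genes$gene_id)],
  max_quasi_h = round(th$max_score[scr$potential], 1),
  n_tumors_ge_cutoff = th$n_ge_cutoff[scr$potential]
)
write.table(pot, "results/screening/potential_targets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Funnel:\n")
print(scr$audit[, c("stage", "n_in", "n_out")], row.names = FALSE)
cat(length(scr$potential), "potential targets carried into validation\n")
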