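#!/usr/bin/env Rscript
# Step 5 — render the two heat maps with their tabular sidecars.
#
# (a) quasi H-scores of the candidate targets across the 20 tumor types
#     (continuous 0-300 scale, undefined cells in grey);
# (b) ordinal IHC levels of the candidates across the 45 normal tissues
#     (per-tissue maximum over cell types).
# Each image gets a *_data.tsv sidecar holding the exact plotted matrix.

library(adcmine)

dataset <- read_dataset("results/dataset")
res <- run_pipeline(dataset)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

order_ids <- res$priorities$gene_id
f1 <- render_score_heatmap(
  res$screening$scores[order_ids, , drop = FALSE],
  "results/figures/candidate_quasi_h_heatmap.png"
)
f2 <- render_normal_heatmap(
  dataset$normal, "results/figures/candidate_normal_heatmap.png",
  gene_order = order_ids
)

cat("Wrote:\n  ", f1$image, "\n  ", f1$sidecar, "\n  ",
    f2$image, "\n  ", f2$sidecar, "\n", sep = "")
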