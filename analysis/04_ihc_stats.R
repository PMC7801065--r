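#!/usr/bin/env Rscript
# Step 4 — experimental-validation statistics on simulated TMA cohorts.
#
# Emulates the urothelial-carcinoma tissue-microarray experiment: 68
# tumors, three 1mm cores each, per-core H-score = intensity x percent
# positive cells, per-tumor H-score = mean of usable cores. The cohort
# means are then compared against the cohort-level (quasi) H-scores by
# one-sample t-test, and per-tumor-type Pearson correlations of candidate
# scores with FPKM are tabulated.

library(adcmine)

seed <- as.integer(Sys.getenv("ADCMINE_SEED", "1"))
dir.create("results/ihc_stats", showWarnings = FALSE, recursive = TRUE)

# --- one-sample t-tests: simulated markers vs their cohort quasi H-score --
markers <- data.frame(
  marker = c("MARKER_A", "MARKER_B"),
  true_mean = c(214.4, 82.0), true_sd = c(86.7, 80.1),
  quasi_h = c(200, 100)
)
rows <- lapply(seq_len(nrow(markers)), function(i) {
  m <- markers[i, ]
  cores <- simulate_tma_cores(68, m$true_mean, m$true_sd,
                              dropout_rate = 0.03, seed = seed + i)
  hs <- tma_h_scores(cores)
  usable <- hs$h_score[!is.na(hs$h_score)]
  tt <- one_sample_t_raw(usable, mu0 = m$quasi_h)
  data.frame(marker = m$marker, n_tumors = length(usable),
             mean_h = round(mean(usable), 1), sd_h = round(sd(usable), 1),
             quasi_h = m$quasi_h,
             mean_difference = round(tt$mean_difference, 1),
             ci_low = round(tt$ci_low, 2), ci_high = round(tt$ci_high, 2),
             p = signif(tt$p_value, 3))
})
ttests <- do.call(rbind, rows)
write.table(ttests, "results/ihc_stats/tma_ttests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("TMA cohort vs cohort-level score, one-sample t-tests:\n")
print(ttests, row.names = FALSE)

# --- per-tumor-type Pearson correlation of scores with FPKM --------------
dataset <- read_dataset("results/dataset")
res <- run_pipeline(dataset)
scores <- res$screening$scores
cors <- lapply(intersect(colnames(scores), unique(dataset$fpkm$tumor_type)),
               function(tt) {
  s <- scores[res$candidates, tt]
  fp <- dataset$fpkm[dataset$fpkm$tumor_type == tt, ]
  f <- setNames(fp$fpkm, fp$gene_id)[res$candidates]
  names(s) <- res$candidates
  ok <- sum(!is.na(s) & !is.na(f))
  if (ok < 3) return(NULL)
  ct <- score_fpkm_correlation(s, f)
  data.frame(tumor_type = tt, r = round(ct$r, 3),
             p = signif(ct$p_value, 3), n = ct$n_pairs)
})
cors <- do.call(rbind, cors)
write.table(cors, "results/ihc_stats/score_fpkm_correlation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nScore-FPKM Pearson correlation across candidate targets:\n")
print(cors, row.names = FALSE)
cat(sum(cors$p < 0.05, na.rm = TRUE), "of", nrow(cors),
    "tumor types significant at p < 0.05\n")
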