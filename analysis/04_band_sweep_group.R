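#!/usr/bin/env Rscript
# The core analysis: exhaustive non-overlapping LF/HF band sweep on a
# 0.02 Hz grid over 0-1 Hz, per-run Pearson correlation of pupil band
# features against the canonical HRV features, Fisher-Z group
# aggregation with cluster-based permutation correction, geometric-mean
# ranking, and the comparison against the two literature band
# definitions. Writes the group table, top-10 and literature comparison
# under results/sweep/.

suppressMessages(library(pupilbands))
seed <- 20260924

ds <- generate_dataset(10, 2, synthetic_run_config(), seed = seed)
cfg <- pipeline_config(band_step = 0.02, order = 48,
                       cluster = cluster_config(n_permutations = 500,
                                                seed = seed))
res <- run_pipeline(ds$runs, cfg, out_dir = "results/sweep")

planted <- c(ds$ground_truth$planted_lf_band[1],
             ds$ground_truth$planted_hf_band[1],
             ds$ground_truth$planted_hf_band[2])
top1 <- res$top[1, ]
cat("top-ranked combination:\n")
print(round(top1[, c("lf_lo", "split", "hf_hi", "r_lf", "r_hf", "r_ratio",
                     "p_lf", "p_hf", "p_ratio", "geo_mean")], 3))
cat(sprintf("planted limits (%.2f, %.2f, %.2f); max recovery error %.2f Hz\n",
            planted[1], planted[2], planted[3],
            max(abs(c(top1$lf_lo, top1$split, top1$hf_hi) - planted))))
cat("literature band definitions on the same cohort:\n")
print(round(res$named[, c("lf_lo", "split", "hf_hi", "r_lf", "r_hf",
                          "r_ratio", "geo_mean")], 3))
if (all(top1$geo_mean > res$named$geo_mean)) {
  cat("the recovered bands outperform both literature definitions\n")
} else {
  cat("NOTE: a literature band matched or outperformed the recovered bands\n")
}
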