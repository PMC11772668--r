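#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 10 subjects x 2 runs of coupled
# RR-interval and pupil-diameter recordings (600 s each, 500 Hz tracker)
# with pupil modulators planted in LF [0.06, 0.29) and HF [0.29, 0.49) Hz.
# The cohort is fully determined by the seed, so later stages regenerate
# it instead of reading bulky raw CSVs; this script records the ground
# truth, a per-run summary, and one example run in the CSV exchange
# format.

suppressMessages(library(pupilbands))
seed <- 20260924

ds <- generate_dataset(10, 2, synthetic_run_config(), seed = seed)
dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(seed = seed, n_subjects = 10, runs_per_subject = 2,
                          ground_truth = ds$ground_truth),
                     "results/ground_truth.json",
                     auto_unbox = TRUE, digits = NA)
# write_run_csv(ds$runs[[1]], "results/example_run")   # uncomment for a full raw-CSV example (~8 MB)

summ <- do.call(rbind, lapply(ds$runs, function(r) {
  data.frame(subject = r$subject, run = r$run,
             n_beats = length(r$rr$beat_times),
             mean_rr_ms = mean(r$rr$intervals),
             pct_invalid = 100 * mean(!r$pupil$valid),
             n_blinks = nrow(attr(r$pupil, "artifacts")$blinks),
             n_spikes = nrow(attr(r$pupil, "artifacts")$spikes))
}))
utils::write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)
cat(sprintf("cohort of %d runs (seed %d)\n", length(ds$runs), seed))
cat(sprintf("beats per run %d-%d; invalid pupil samples %.1f-%.1f%%; blinks %d-%d\n",
            min(summ$n_beats), max(summ$n_beats),
            min(summ$pct_invalid), max(summ$pct_invalid),
            min(summ$n_blinks), max(summ$n_blinks)))
cat(sprintf("planted bands: LF [%.2f, %.2f) Hz, HF [%.2f, %.2f) Hz\n",
            ds$ground_truth$planted_lf_band[1], ds$ground_truth$planted_lf_band[2],
            ds$ground_truth$planted_hf_band[1], ds$ground_truth$planted_hf_band[2]))
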