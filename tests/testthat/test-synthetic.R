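test_that("modulators are deterministic, standardized, and band-placed", {
  spec <- modulator_spec(0.10, 0.04)
  m1 <- make_band_limited_modulator(spec, 600, 8, 42)
  m2 <- make_band_limited_modulator(spec, 600, 8, 42)
  expect_identical(m1$values, m2$values)
  m3 <- make_band_limited_modulator(spec, 600, 8, 43)
  expect_false(identical(m1$values, m3$values))

  # variance and spectral placement via the averaged periodogram over seeds
  vars <- numeric(20); inband <- numeric(20); avg <- 0
  for (s in 1:20) {
    m <- make_band_limited_modulator(spec, 600, 8, s)
    vars[s] <- var(m$values)
    pg <- spec.pgram(ts(m$values, frequency = 8), plot = FALSE, taper = 0)
    avg <- avg + pg$spec / 20
    inband[s] <- sum(pg$spec[pg$freq >= 0.08 & pg$freq <= 0.12]) / sum(pg$spec)
  }
  fpeak <- pg$freq[which.max(avg)]
  expect_true(fpeak >= 0.08 && fpeak <= 0.12)
  expect_true(all(abs(vars - 1) < 0.05))
  expect_gt(mean(inband), 0.6)

  expect_error(make_band_limited_modulator(modulator_spec(3.5, 1.5), 10, 8, 1),
               "Nyquist")
  expect_error(modulator_spec(0.05, 0.2), "below 0 Hz")
})

test_that("zero-gain RR synthesis gives exact mean intervals and beat count", {
  cfg <- synthetic_run_config(duration = 600, rr_mean = 1000,
                              rr_lf = modulator_spec(0.1, 0.05, 0),
                              rr_hf = modulator_spec(0.3, 0.05, 0),
                              seed = 1)
  rr <- synthesize_rr(cfg)
  expect_true(all(abs(rr$intervals - 1000) < 1e-9))
  expect_equal(length(rr$beat_times), 601, tolerance = 0)
  expect_lte(max(rr$beat_times), 600)
})

test_that("LF-only RR modulation concentrates HRV power in the LF band", {
  cfg <- synthetic_run_config(duration = 600, seed = 2,
                              rr_lf = modulator_spec(0.10, 0.04, 0.06),
                              rr_hf = modulator_spec(0.30, 0.05, 0))
  hrv <- preprocess_hrv(synthesize_rr(cfg))
  wp <- window_psds(sliding_windows(hrv, 180, 10), 16)
  f <- hrv_feature_series(wp)
  expect_gt(median(f$ratio), 3)
})

test_that("out-of-bounds RR configurations are rejected", {
  cfg <- synthetic_run_config(seed = 3,
                              rr_lf = modulator_spec(0.10, 0.05, 0.9))
  expect_error(synthesize_rr(cfg), "physiological bounds")
})

test_that("artifact-free pupil synthesis reduces to the deterministic baseline", {
  cfg <- synthetic_run_config(duration = 400, pupil_fs = 50, seed = 4,
                              pupil_lf = modulator_spec(0.175, 0.23, 0),
                              pupil_hf = modulator_spec(0.39, 0.20, 0),
                              pink_noise_sd = 0, broadband_sd = 0,
                              blink_rate = 0, spike_outlier_rate = 0)
  p <- synthesize_pupil(cfg)
  expect_true(all(p$values == cfg$pupil_baseline))
  expect_true(all(p$valid))
})

test_that("blink counts follow the Poisson rate and mask matches blink time", {
  cfg <- synthetic_run_config(duration = 600, pupil_fs = 60, seed = 5,
                              blink_rate = 6, spike_outlier_rate = 0)
  p <- synthesize_pupil(cfg)
  blinks <- attr(p, "artifacts")$blinks
  expect_true(abs(nrow(blinks) - 60) <= 16)   # Poisson 2 sigma
  # invalid fraction approximates injected blink time
  dur_in <- sum(pmin(blinks$onset + blinks$duration, 600) - blinks$onset)
  frac <- sum(!p$valid) / length(p$valid)
  expect_lt(abs(frac - dur_in / 600) / (dur_in / 600), 0.10)
})

test_that("datasets have the right shape and are seed-reproducible", {
  cfg <- quick_cfg()
  ds <- generate_dataset(2, 2, cfg, seed = 9)
  expect_length(ds$runs, 4)
  expect_equal(ds$ground_truth$planted_lf_band, c(0.06, 0.29))
  expect_equal(ds$ground_truth$planted_hf_band, c(0.29, 0.49))
  ds2 <- generate_dataset(2, 2, cfg, seed = 9)
  expect_identical(ds$runs[[3]]$pupil$values, ds2$runs[[3]]$pupil$values)
  expect_identical(ds$runs[[2]]$rr$beat_times, ds2$runs[[2]]$rr$beat_times)
  ds3 <- generate_dataset(2, 2, cfg, seed = 10)
  expect_false(identical(ds$runs[[1]]$pupil$values, ds3$runs[[1]]$pupil$values))
})

test_that("run CSV export round-trips through the readers", {
  ds <- generate_dataset(1, 1, quick_cfg(seed = 6), seed = 6)
  dir <- tempfile("runs")
  paths <- write_run_csv(ds$runs[[1]], dir)
  expect_true(all(file.exists(paths)))
  p <- read_pupil_csv(paths["pupil"])
  expect_equal(p$values, ds$runs[[1]]$pupil$values)
  expect_equal(p$valid, ds$runs[[1]]$pupil$valid)
  expect_equal(p$fs, ds$runs[[1]]$pupil$fs, tolerance = 1e-6)
  b <- read_beats_csv(paths["beats"])
  expect_equal(b$beat_times, ds$runs[[1]]$rr$beat_times)
  # deterministic bytes for fixed seed
  dir2 <- tempfile("runs2")
  ds_b <- generate_dataset(1, 1, quick_cfg(seed = 6), seed = 6)
  paths2 <- write_run_csv(ds_b$runs[[1]], dir2)
  expect_identical(readLines(paths[["pupil"]]), readLines(paths2[["pupil"]]))
  unlink(c(dir, dir2), recursive = TRUE)
})
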