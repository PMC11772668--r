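test_that("margin masking covers the stated window and merges close spans", {
  fs <- 100
  n <- 500
  valid <- rep(TRUE, n)
  valid[201:211] <- FALSE               # invalid span [2.00, 2.10] s
  sig <- sampled_signal(rnorm(n), fs, 0, valid)
  out <- mask_invalid_with_margin(sig, 100)
  tt <- signal_times(out)
  expect_true(all(!out$valid[tt >= 1.9 & tt <= 2.2]))

  # two spans 150 ms apart with 100 ms margins merge into one
  valid2 <- rep(TRUE, n)
  valid2[101:110] <- FALSE
  valid2[126:135] <- FALSE              # gap of 15 samples = 150 ms
  out2 <- mask_invalid_with_margin(sampled_signal(rnorm(n), fs, 0, valid2), 100)
  r <- rle(!out2$valid)
  expect_equal(sum(r$values), 1L)

  # no invalid samples: identity
  clean <- sampled_signal(rnorm(50), fs)
  expect_equal(mask_invalid_with_margin(clean, 100)$valid, clean$valid)
})

test_that("margin masking agrees with an interval-union oracle", {
  set.seed(7)
  fs <- 40; n <- 2000
  valid <- rep(TRUE, n)
  for (k in 1:12) { i <- sample(n - 20, 1); valid[i:(i + sample(5:15, 1))] <- FALSE }
  sig <- sampled_signal(rnorm(n), fs, 0, valid)
  out <- mask_invalid_with_margin(sig, 100)
  tt <- signal_times(sig)
  w <- 0.100
  oracle <- rep(FALSE, n)
  for (i in which(!valid)) oracle <- oracle | (tt >= tt[i] - w - 1e-12 & tt <= tt[i] + w + 1e-12)
  expect_equal(!out$valid, oracle)
})

test_that("shape-preserving cubic fill restores ramps and never overshoots", {
  fs <- 10
  x <- seq(0, 10, by = 1 / fs)
  valid <- rep(TRUE, length(x))
  valid[40:55] <- FALSE
  ramp <- sampled_signal(2 * x + 1, fs, 0, valid)
  filled <- fill_gaps_shape_preserving_cubic(ramp)
  expect_lt(max(abs(filled$values - (2 * x + 1))), 1e-9)
  expect_true(all(filled$valid))

  # monotone data: interpolant stays within the neighbouring valid values
  y <- cumsum(abs(rnorm(length(x))))
  sig <- sampled_signal(y, fs, 0, valid)
  out <- fill_gaps_shape_preserving_cubic(sig)
  expect_true(all(out$values[40:55] >= y[39] - 1e-12))
  expect_true(all(out$values[40:55] <= y[56] + 1e-12))

  # no gaps: identity
  all_ok <- sampled_signal(y, fs)
  expect_identical(fill_gaps_shape_preserving_cubic(all_ok)$values, y)
  # leading invalid samples must be trimmed first
  bad_lead <- sampled_signal(y, fs, 0, c(FALSE, valid[-1]))
  expect_error(fill_gaps_shape_preserving_cubic(bad_lead), "trimmed")
})

test_that("downsampling preserves slow content and rejects fast content", {
  dc <- sampled_signal(rep(4.2, 500 * 60 + 1), 500)
  out <- downsample(dc, 8)
  expect_equal(out$fs, 8)
  expect_lt(max(abs(out$values - 4.2)), 1e-6)

  s <- sine_signal(0.2, 500, 120)
  out2 <- downsample(s, 8)
  expect_lt(abs(central_amp(out2$values) - 1), 0.02)

  fast <- sine_signal(10, 500, 120)
  out3 <- downsample(fast, 8)
  mid <- out3$values[100:(length(out3$values) - 100)]
  expect_lt(sqrt(mean(mid^2)), 0.05 * sqrt(0.5))
  expect_error(downsample(out3, 8), "below")
})

test_that("drift high-pass rejects DC and drift but passes 0.1 Hz", {
  dc <- sampled_signal(rep(3.7, 4800), 8)
  expect_lt(max(abs(highpass(dc)$values)), 1e-6 * 3.7)

  s <- sine_signal(0.1, 8, 600)
  out <- highpass(s)
  expect_lt(abs(central_amp(out$values) - 1), 0.02)

  drift <- sampled_signal(0.005 * seq(0, 600, by = 1 / 8) + 2, 8)
  out2 <- highpass(drift)
  expect_lt(var(out2$values), 0.1 * var(drift$values))
})

test_that("full pupil chain is near-transparent on clean band-passed input", {
  # bounded clean input (tones well inside the Tukey fences, tiny noise):
  # the outlier stage has nothing to flag and the chain reduces to
  # downsample + high-pass
  set.seed(3)
  tt <- seq(0, 400, by = 1 / 50)
  raw <- sampled_signal(4.5 + 0.3 * sin(2 * pi * 0.2 * tt) +
                          0.15 * sin(2 * pi * 0.35 * tt) +
                          0.02 * rnorm(length(tt)), 50)
  out <- preprocess_pupil(raw)
  expect_equal(out$fs, 8)
  expect_true(all(out$valid))
  rep <- attr(out, "report")
  expect_lt(rep$n_flagged_8hz / rep$n_samples_out, 0.03)
  ref <- highpass(downsample(raw, 8))
  expect_equal(out$t0, ref$t0)
  n <- min(length(out$values), length(ref$values))
  d <- out$values[1:n] - ref$values[1:n]
  expect_lt(sqrt(mean(d^2)), 0.03 * sd(ref$values))
})

test_that("a planted 0.25 Hz tone survives the full chain with small peak shift", {
  cfg <- synthetic_run_config(duration = 400, pupil_fs = 50, seed = 11,
                              blink_rate = 6, spike_outlier_rate = 1,
                              pupil_lf = modulator_spec(0.25, 0.02, 0.3),
                              pupil_hf = modulator_spec(0.6, 0.02, 0),
                              pink_noise_sd = 0.05, broadband_sd = 0,
                              envelope_sigma = 0)
  out <- preprocess_pupil(synthesize_pupil(cfg))
  wins <- sliding_windows(out, 180, 4)
  wp <- window_psds(wins, order = 48)
  peak <- wp$freqs[which.max(colMeans(wp$density))]
  expect_lt(abs(peak - 0.25), 0.02)
})
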