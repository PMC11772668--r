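test_that("combination enumeration matches the combinatorial count", {
  c25 <- enumerate_combinations(0.25, 1.0)
  expect_equal(nrow(c25), choose(5, 3))        # 10
  expect_equal(nrow(enumerate_combinations(0.5, 1.0)), 1)
  c10 <- enumerate_combinations(0.1, 1.0)
  expect_equal(nrow(c10), choose(11, 3))
  expect_true(all(c10$lf_lo < c10$split & c10$split < c10$hf_hi))
  expect_error(enumerate_combinations(0.03, 1.0), "integer multiple")
})

test_that("the full 0.01 Hz grid has C(101, 3) combinations in stable order", {
  cmb <- enumerate_combinations(0.01, 1.0)
  expect_equal(nrow(cmb), 166650)
  expect_equal(nrow(cmb), choose(101, 3))
  # lexicographic order
  key <- cmb$i * 1e6 + cmb$j * 1e3 + cmb$k
  expect_true(all(diff(key) > 0))
  # the canonical literature combos are on the grid
  expect_true(any(abs(cmb$lf_lo - 0.04) < 1e-9 & abs(cmb$split - 0.15) < 1e-9 &
                  abs(cmb$hf_hi - 0.40) < 1e-9))
})

test_that("HRV features separate LF-only from HF-only modulation", {
  mk <- function(lf_gain, hf_gain, seed) {
    cfg <- quick_cfg(seed = seed,
                     rr_lf = modulator_spec(0.10, 0.06, lf_gain),
                     rr_hf = modulator_spec(0.30, 0.08, hf_gain))
    hrv <- preprocess_hrv(synthesize_rr(cfg))
    wp <- window_psds(sliding_windows(hrv, 180, 4), 16)
    hrv_feature_series(wp)
  }
  lf_only <- mk(0.06, 0, 21)
  expect_gt(median(lf_only$ratio), 5)
  hf_only <- mk(0, 0.06, 22)
  expect_lt(median(hf_only$ratio), 0.5)
})

test_that("white-noise HRV has LF/HF near the bandwidth ratio", {
  set.seed(30)
  ratios <- replicate(20, {
    w <- sampled_signal(rnorm(350 * 8 + 1), 8)
    wp <- window_psds(sliding_windows(w, 180, 30), 16)
    f <- hrv_feature_series(wp)
    mean(f$ratio)
  })
  expect_lt(abs(mean(ratios) - 0.11 / 0.25), 0.12)
})

test_that("cumulative-power matrix reconstructs band powers exactly", {
  set.seed(12)
  sig <- sampled_signal(rnorm(400 * 8 + 1), 8)
  wp <- window_psds(sliding_windows(sig, 180, 10), 16)
  edges <- seq(0, 1, by = 0.01)
  cm <- pupil_cumpower_matrix(wp, edges)
  expect_true(all(diff(t(cm)) >= -1e-12))
  # random combos vs direct per-window band_power
  set.seed(13)
  for (rep in 1:25) {
    idx <- sort(sample(101, 3))
    direct <- vapply(seq_len(nrow(wp$cum)), function(i) {
      psd <- structure(list(freqs = wp$freqs, density = wp$density[i, ],
                            cum_power = wp$cum[i, ]), class = "psd_estimate")
      band_power(psd, edges[idx[1]], edges[idx[2]])
    }, numeric(1))
    expect_lt(max(abs((cm[, idx[2]] - cm[, idx[1]]) - direct)) /
                max(direct), 1e-10)
  }
  # last edge equals power in [0, 1)
  psd1 <- structure(list(freqs = wp$freqs, density = wp$density[1, ],
                         cum_power = wp$cum[1, ]), class = "psd_estimate")
  expect_equal(unname(cm[1, 101]), band_power(psd1, 0, 1.0))
})

test_that("per-run correlations behave on self, negation, and misalignment", {
  set.seed(14)
  nwin <- 50
  edges <- seq(0, 1, by = 0.2)
  cum <- t(apply(matrix(abs(rnorm(nwin * length(edges))), nwin), 1, cumsum))
  combos <- enumerate_combinations(0.2, 1.0)
  lf <- cum[, combos$j[1]] - cum[, combos$i[1]]
  hf <- cum[, combos$k[1]] - cum[, combos$j[1]]
  hrv <- data.frame(lf = lf, hf = hf, ratio = lf / hf)
  res <- per_run_correlation(cum, hrv, combos)
  expect_equal(res$r_lf[1], 1)
  expect_lt(res$p_lf[1], 1e-20)
  hrv_neg <- data.frame(lf = -lf, hf = -hf, ratio = lf / hf)
  res2 <- per_run_correlation(cum, hrv_neg, combos)
  expect_equal(res2$r_lf[1], -1)
  expect_error(per_run_correlation(cum[1:10, ], hrv, combos), "aligned")
})

test_that("sweep path equals brute-force recomputation on a coarse grid", {
  set.seed(15)
  sig <- sampled_signal(rnorm(400 * 8 + 1), 8)
  wp <- window_psds(sliding_windows(sig, 180, 10), 16)
  hrv <- data.frame(lf = rnorm(nrow(wp$cum)), hf = rnorm(nrow(wp$cum)),
                    ratio = abs(rnorm(nrow(wp$cum))))
  combos <- enumerate_combinations(0.1, 1.0)
  cm <- pupil_cumpower_matrix(wp, attr(combos, "edges"))
  res <- per_run_correlation(cm, hrv, combos)
  for (ri in sample(nrow(combos), 20)) {
    lf <- cm[, combos$j[ri]] - cm[, combos$i[ri]]
    hf <- cm[, combos$k[ri]] - cm[, combos$j[ri]]
    expect_lt(abs(res$r_lf[ri] - cor(lf, hrv$lf)), 1e-10)
    expect_lt(abs(res$r_hf[ri] - cor(hf, hrv$hf)), 1e-10)
    expect_lt(abs(res$r_ratio[ri] - cor(lf / hf, hrv$ratio)), 1e-10)
    p_oracle <- cor.test(lf, hrv$lf)$p.value
    expect_lt(abs(res$p_lf[ri] - p_oracle), 1e-10)
  }
})

test_that("Spearman correlations are invariant under monotone transforms", {
  set.seed(16)
  nwin <- 60
  edges <- seq(0, 1, by = 0.25)
  cum <- t(apply(matrix(abs(rnorm(nwin * length(edges))), nwin), 1, cumsum))
  combos <- enumerate_combinations(0.25, 1.0)
  hrv <- data.frame(lf = rnorm(nwin), hf = rnorm(nwin), ratio = rnorm(nwin))
  r1 <- per_run_correlation(cum, hrv, combos, method = "spearman")
  hrv2 <- data.frame(lf = exp(hrv$lf), hf = hrv$hf^3 + 2 * hrv$hf,
                     ratio = atan(hrv$ratio))
  r2 <- per_run_correlation(cum, hrv2, combos, method = "spearman")
  expect_equal(r1$r_lf, r2$r_lf, tolerance = 1e-12)
  expect_equal(r1$r_hf, r2$r_hf, tolerance = 1e-12)
  expect_equal(r1$r_ratio, r2$r_ratio, tolerance = 1e-12)
})
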