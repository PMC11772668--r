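test_that("Fisher transform round-trips and matches closed forms", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  rs <- seq(-0.999, 0.999, by = 0.037)
  expect_lt(max(abs(fisher_z_inv(fisher_z(rs)) - rs)), 1e-12)
  expect_error(fisher_z(1), "< 1")
})

test_that("run aggregation weights by n - 3 and respects symmetry", {
  a <- aggregate_runs(rep(0.4, 5), c(10, 50, 100, 20, 400))
  expect_equal(a$r_group, 0.4)
  b <- aggregate_runs(c(0.3, -0.3), c(50, 50))
  expect_equal(b$r_group, 0)
  expect_gt(b$p, 0.99)
  # unequal n pulls the mean toward the better-sampled run
  d <- aggregate_runs(c(0.2, 0.6), c(103, 13))
  expect_lt(abs(d$r_group - 0.2), abs(d$r_group - 0.6))
  # oracle: hand-computed weighted z mean
  z <- (100 * atanh(0.2) + 10 * atanh(0.6)) / 110
  expect_equal(d$r_group, tanh(z))
  expect_equal(d$p, 2 * pnorm(-abs(z * sqrt(110))))
  # equal n reduces to the plain mean of z
  e <- aggregate_runs(c(0.1, 0.5, 0.3), c(40, 40, 40))
  expect_equal(e$r_group, tanh(mean(atanh(c(0.1, 0.5, 0.3)))))
  expect_error(aggregate_runs(c(0.2, NA), c(10, 10)), "at least 2")
})

test_that("percent significant runs counts p < alpha", {
  expect_equal(pct_significant_runs(rep(0.001, 8)), 100)
  expect_equal(pct_significant_runs(c(0.01, 0.2, 0.03, 0.8)), 50)
  expect_true(is.na(pct_significant_runs(c(NA, NA))))
})

test_that("geometric mean matches worked examples and edge rules", {
  expect_equal(geometric_mean_score(0.279, 0.168, 0.286),
               (0.279 * 0.168 * 0.286)^(1 / 3))
  expect_equal(geometric_mean_score(0.5, 0.5, 0.5), 0.5)
  expect_true(is.na(geometric_mean_score(0.5, -0.1, 0.5)))
  expect_true(is.na(geometric_mean_score(0.5, NA, 0.5)))
})

test_that("cluster correction controls structure on the lattice", {
  combos <- enumerate_combinations(0.2, 1.0)
  n_runs <- 12
  set.seed(20)
  # planted coherent signal in one combo and its lattice neighbours
  target <- which(abs(combos$lf_lo - 0.2) < 1e-9 &
                  abs(combos$split - 0.4) < 1e-9 &
                  abs(combos$hf_hi - 0.6) < 1e-9)
  nb <- which(abs(combos$i - combos$i[target]) + abs(combos$j - combos$j[target]) +
              abs(combos$k - combos$k[target]) <= 1)
  Z <- matrix(rnorm(n_runs * nrow(combos), 0, 0.15), n_runs)
  Z[, nb] <- Z[, nb] + 0.5
  ns <- rep(100, n_runs)
  cc <- cluster_permutation_correct(Z, ns, combos,
                                    cluster_config(n_permutations = 300, seed = 4))
  expect_lt(max(cc$p_corrected[nb]), 0.05)
  # all members of one cluster share an identical corrected p
  cl <- cc$cluster_id[nb]
  expect_true(all(!is.na(cl)))
  for (cid in unique(cl))
    expect_equal(length(unique(cc$p_corrected[which(cc$cluster_id == cid)])), 1L)
  # corrected p never below the uncorrected cluster-forming p
  sup <- which(!is.na(cc$cluster_id))
  expect_true(all(cc$p_corrected[sup] >= cc$p_uncorrected[sup] - 1e-12 |
                  cc$p_corrected[sup] >= 1 / 301))
  expect_true(all(cc$p_corrected[is.na(cc$cluster_id)] == 1))
  expect_error(cluster_permutation_correct(Z[1, , drop = FALSE], ns[1], combos,
                                           cluster_config()),
               "2 runs")
  expect_error(cluster_config(n_permutations = 50), ">= 100")
})

test_that("ranking is deterministic with documented tie-breaks", {
  tab <- data.frame(lf_lo = c(0.1, 0.2, 0.3, 0.4),
                    split = c(0.3, 0.4, 0.5, 0.6),
                    hf_hi = c(0.5, 0.6, 0.7, 0.8),
                    r_lf = c(0.5, 0.5, 0.4, 0.3),
                    r_hf = c(0.5, 0.5, 0.6, 0.2),
                    r_ratio = c(0.5, 0.5, 0.4, -0.1))
  tab$geo_mean <- geometric_mean_score(tab$r_lf, tab$r_hf, tab$r_ratio)
  top <- rank_top(tab, 10)
  expect_equal(nrow(top), 3)           # the negative-r combo is unscorable
  expect_true(all(diff(top$geo_mean) <= 1e-15))
  # exact ties resolved lexicographically by the limits
  tied <- tab[c(2, 1), ]; tied$geo_mean <- 0.5
  tied$r_lf <- tied$r_hf <- tied$r_ratio <- 0.5
  expect_equal(rank_top(tied, 2)$lf_lo, c(0.1, 0.2))
})

test_that("named-combination lookup validates the grid", {
  tab <- data.frame(lf_lo = 0.04, split = 0.15, hf_hi = 0.40,
                    r_lf = 0.3, r_hf = 0.2, r_ratio = 0.25, geo_mean = 0.25)
  hit <- evaluate_named_combos(tab, list(c(0.04, 0.15, 0.40)))
  expect_equal(hit$r_lf, 0.3)
  expect_error(evaluate_named_combos(tab, list(c(0.045, 0.15, 0.40))),
               "not aligned")
  expect_error(evaluate_named_combos(tab, list(c(0.05, 0.15, 0.45))),
               "not present")
})
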