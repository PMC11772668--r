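# Group-level aggregation of per-run correlations: Fisher-Z weighted means,
# cluster-based permutation correction over the band-combination lattice,
# percentage of significant runs, geometric-mean scoring and ranking.

#' Fisher Z transformation and its inverse
#'
#' `z = atanh(r)`, the variance-stabilizing transform that allows
#' correlation coefficients from runs of different lengths to be averaged;
#' the inverse is `tanh(z)`.
#'
#' @param r correlation coefficient(s), `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-Z value(s).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Aggregate per-run correlations across a cohort
#'
#' Weighted mean in Fisher-Z space with the variance-optimal weights
#' `n_i - 3`, transformed back with the inverse Fisher transform. The
#' group p-value is two-sided from the normal statistic
#' `zbar * sqrt(sum(w))`.
#'
#' @param rs per-run correlation coefficients (NA allowed; dropped).
#' @param ns per-run window counts (each >= 4 for defined runs).
#' @return list with `r_group`, `p`, `z_stat`, `n_runs`.
#' @export
aggregate_runs <- function(rs, ns) {
  ok <- is.finite(rs)
  if (sum(ok) < 2L) stop("need at least 2 runs with defined correlations")
  rs <- rs[ok]; ns <- ns[ok]
  if (any(ns < 4)) stop("every run must contribute at least 4 windows")
  w <- ns - 3
  zbar <- sum(w * fisher_z(rs)) / sum(w)
  z_stat <- zbar * sqrt(sum(w))
  list(r_group = fisher_z_inv(zbar),
       p = 2 * stats::pnorm(abs(z_stat), lower.tail = FALSE),
       z_stat = z_stat, n_runs = sum(ok))
}

#' Percentage of runs with a significant correlation
#'
#' @param ps per-run p-values (NA dropped).
#' @param alpha significance level (default 0.05).
#' @return Percentage in `[0, 100]`, or NA if no run has a defined p.
#' @export
pct_significant_runs <- function(ps, alpha = 0.05) {
  ps <- ps[is.finite(ps)]
  if (length(ps) == 0L) return(NA_real_)
  100 * mean(ps < alpha)
}

#' Geometric-mean score of the three feature correlations
#'
#' `(r_lf * r_hf * r_ratio)^(1/3)`, the sweep's ranking objective; defined
#' only when all three group correlations are positive (a combination that
#' tracks HRV in inconsistent directions cannot be ranked).
#'
#' @param r_lf,r_hf,r_ratio group correlation values (vectorized).
#' @return The score, or NA where any input is missing or non-positive.
#' @export
geometric_mean_score <- function(r_lf, r_hf, r_ratio) {
  ok <- is.finite(r_lf) & is.finite(r_hf) & is.finite(r_ratio) &
    r_lf > 0 & r_hf > 0 & r_ratio > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- (r_lf[ok] * r_hf[ok] * r_ratio[ok])^(1 / 3)
  out
}

#' Cluster-permutation configuration
#'
#' @param alpha cluster-forming and family-wise significance level
#'   (default 0.05).
#' @param n_permutations number of sign-flip permutations (>= 100;
#'   default 500).
#' @param seed integer seed for the permutation draws.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(alpha = 0.05, n_permutations = 500, seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  if (n_permutations < 100) stop("`n_permutations` must be >= 100")
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

# adjacency on the combination lattice: two combinations are neighbours iff
# they differ by exactly one grid step in exactly one of the three limits.
# Returns a 2-column matrix of combo row indices.
lattice_edges <- function(combos) {
  M <- max(combos$k) + 1L
  key <- function(i, j, k) i + M * (j + M * k)
  keys <- key(combos$i, combos$j, combos$k)
  edges <- NULL
  for (dim in 1:3) {
    di <- c(dim == 1, dim == 2, dim == 3)
    nb <- key(combos$i + di[1], combos$j + di[2], combos$k + di[3])
    m <- match(nb, keys)
    ok <- !is.na(m)
    edges <- rbind(edges, cbind(which(ok), m[ok]))
  }
  edges
}

# union-find connected components over supra-threshold nodes
uf_components <- function(n_nodes, edges) {
  parent <- seq_len(n_nodes)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# cluster masses (sum of |stat|) of supra-threshold combos; returns list of
# cluster id per combo (NA if sub-threshold) and mass per cluster
cluster_masses <- function(stat, thr, edges) {
  supra <- which(is.finite(stat) & abs(stat) > thr)
  if (length(supra) == 0L)
    return(list(id = rep(NA_integer_, length(stat)), mass = numeric(0)))
  pos <- match(seq_along(stat), supra)       # combo -> supra index
  sub <- edges[!is.na(pos[edges[, 1]]) & !is.na(pos[edges[, 2]]), ,
               drop = FALSE]
  sub <- cbind(pos[sub[, 1]], pos[sub[, 2]])
  comp <- uf_components(length(supra), sub)
  comp <- match(comp, unique(comp))
  mass <- as.numeric(tapply(abs(stat[supra]), comp, sum))
  id <- rep(NA_integer_, length(stat))
  id[supra] <- comp
  list(id = id, mass = mass)
}

# weighted group z statistic per combo, with NA runs dropped per combo
group_z_stat <- function(Z, w, signs = NULL) {
  if (is.null(signs)) signs <- rep(1, length(w))
  W <- matrix(w * signs, nrow(Z), ncol(Z))
  ok <- is.finite(Z)
  Zw <- Z; Zw[!ok] <- 0
  num <- colSums(W * Zw)
  den <- sqrt(colSums(abs(W) * ok))
  ifelse(den > 0, num / den, NA_real_)
}

#' Cluster-based permutation correction over the combination lattice
#'
#' Computes the weighted group z statistic per combination, thresholds at
#' the two-sided uncorrected `alpha`, forms clusters of lattice-adjacent
#' supra-threshold combinations (neighbours differ by one grid step in one
#' limit), scores each cluster by the sum of absolute statistics, and
#' calibrates cluster masses against the permutation null of the maximum
#' cluster mass under random sign flips of each run's z vector. Every
#' combination in a cluster inherits the cluster's corrected p; combos
#' below threshold get corrected p = 1.
#'
#' @param Z runs x combos matrix of Fisher-Z per-run correlations.
#' @param ns per-run window counts (weights are `ns - 3`).
#' @param combos data.frame from [enumerate_combinations()] matching the
#'   columns of `Z`.
#' @param cfg a [cluster_config()].
#' @return list with `p_corrected` (per combo), `z_stat`, `p_uncorrected`,
#'   `cluster_id`, and `null_max_mass` (the permutation distribution).
#' @export
cluster_permutation_correct <- function(Z, ns, combos, cfg = cluster_config()) {
  stopifnot(inherits(cfg, "cluster_config"))
  if (!is.matrix(Z) || nrow(Z) < 2L)
    stop("`Z` must be a runs x combos matrix with at least 2 runs")
  if (ncol(Z) != nrow(combos)) stop("`Z` and `combos` do not match")
  w <- ns - 3
  thr <- stats::qnorm(1 - cfg$alpha / 2)
  edges <- lattice_edges(combos)
  stat <- group_z_stat(Z, w)
  obs <- cluster_masses(stat, thr, edges)
  p_unc <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  null_max <- numeric(cfg$n_permutations)
  perm_signs <- with_seed(cfg$seed, {
    matrix(sample(c(-1, 1), cfg$n_permutations * nrow(Z), replace = TRUE),
           nrow = cfg$n_permutations)
  })
  for (b in seq_len(cfg$n_permutations)) {
    sp <- group_z_stat(Z, w, perm_signs[b, ])
    cm <- cluster_masses(sp, thr, edges)
    null_max[b] <- if (length(cm$mass)) max(cm$mass) else 0
  }
  p_corr <- rep(1, ncol(Z))
  if (length(obs$mass)) {
    pc <- vapply(obs$mass,
                 function(m) (1 + sum(null_max >= m)) /
                   (cfg$n_permutations + 1),
                 numeric(1))
    in_cl <- !is.na(obs$id)
    p_corr[in_cl] <- pc[obs$id[in_cl]]
  }
  list(p_corrected = p_corr, z_stat = stat, p_uncorrected = p_unc,
       cluster_id = obs$id, null_max_mass = null_max)
}

#' Group-level sweep aggregation
#'
#' Combines the per-run sweep tables of a cohort into one group table:
#' Fisher-Z weighted mean correlation per combination and feature,
#' cluster-corrected p-values, percentage of runs with a significant
#' per-run correlation, and the geometric-mean score.
#'
#' @param run_results list of per-run data.frames from
#'   [per_run_correlation()] (identical combination order).
#' @param combos data.frame from [enumerate_combinations()].
#' @param cfg a [cluster_config()].
#' @return data.frame with one row per combination: the limits, `r_lf`,
#'   `r_hf`, `r_ratio`, `p_lf`, `p_hf`, `p_ratio` (cluster-corrected),
#'   `pct_lf`, `pct_hf`, `pct_ratio`, `geo_mean`.
#' @export
aggregate_sweep <- function(run_results, combos, cfg = cluster_config()) {
  if (length(run_results) < 2L) stop("need at least 2 runs")
  out <- combos[, c("lf_lo", "split", "hf_hi")]
  ns <- vapply(run_results, function(d) d$n[1], numeric(1))
  for (feat in c("lf", "hf", "ratio")) {
    R <- do.call(rbind, lapply(run_results, function(d) d[[paste0("r_", feat)]]))
    P <- do.call(rbind, lapply(run_results, function(d) d[[paste0("p_", feat)]]))
    R[!is.finite(R) | abs(R) >= 1] <- NA
    Z <- atanh(R)
    cc <- cluster_permutation_correct(Z, ns, combos, cfg)
    w <- ns - 3
    W <- matrix(w, nrow(Z), ncol(Z))
    ok <- is.finite(Z)
    Zw <- Z; Zw[!ok] <- 0
    r_group <- tanh(colSums(W * Zw) / pmax(colSums(W * ok), .Machine$double.eps))
    r_group[colSums(ok) < 2] <- NA
    out[[paste0("r_", feat)]] <- r_group
    out[[paste0("p_", feat)]] <- cc$p_corrected
    out[[paste0("p_unc_", feat)]] <- cc$p_uncorrected
    out[[paste0("pct_", feat)]] <- apply(P, 2, pct_significant_runs,
                                         alpha = cfg$alpha)
  }
  out$geo_mean <- geometric_mean_score(out$r_lf, out$r_hf, out$r_ratio)
  out
}

#' Top-k ranking of band combinations
#'
#' Descending by geometric mean; ties broken by `r_ratio`, `r_lf`, `r_hf`
#' descending, then lexicographically by the combination limits, so the
#' ordering is deterministic across reruns.
#'
#' @param results group table from [aggregate_sweep()].
#' @param k number of combinations to keep (default 10).
#' @return The top rows of `results` (fewer if fewer are scorable).
#' @export
rank_top <- function(results, k = 10) {
  scored <- results[is.finite(results$geo_mean), , drop = FALSE]
  if (nrow(scored) == 0L) {
    out <- scored
    attr(out, "status") <- "no scorable combinations"
    return(out)
  }
  ord <- order(-scored$geo_mean, -scored$r_ratio, -scored$r_lf,
               -scored$r_hf, scored$lf_lo, scored$split, scored$hf_hi)
  utils::head(scored[ord, , drop = FALSE], k)
}

#' Metrics for named (literature) band combinations
#'
#' Looks up the group-table rows of specific combinations -- by default
#' the two band definitions most common in the pupillography literature --
#' so they can be compared with the top-ranked ones.
#'
#' @param results group table from [aggregate_sweep()].
#' @param combos list of numeric triples `c(lf_lo, split, hf_hi)`.
#' @param step the sweep grid step (for the alignment check).
#' @return The matching rows of `results`, in the order given.
#' @export
evaluate_named_combos <- function(results,
                                  combos = list(c(0.04, 0.15, 0.40),
                                                c(0.05, 0.15, 0.45)),
                                  step = 0.01) {
  rows <- vapply(combos, function(cb) {
    if (any(abs(cb / step - round(cb / step)) > 1e-9))
      stop("combination (", paste(cb, collapse = ", "),
           ") is not aligned to the ", step, " Hz grid")
    hit <- which(abs(results$lf_lo - cb[1]) < 1e-9 &
                 abs(results$split - cb[2]) < 1e-9 &
                 abs(results$hf_hi - cb[3]) < 1e-9)
    if (length(hit) != 1L)
      stop("combination (", paste(cb, collapse = ", "),
           ") not present in the sweep results")
    hit
  }, integer(1))
  results[rows, , drop = FALSE]
}
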