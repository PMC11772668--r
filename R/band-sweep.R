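# Exhaustive sweep of non-overlapping LF/HF band-limit combinations on a
# regular frequency grid, and per-run correlation of pupil band-power
# features against the canonical HRV features.

#' Canonical HRV frequency bands
#'
#' LF 0.04-0.15 Hz and HF 0.15-0.40 Hz, the established bands of the HRV
#' literature; used for the fixed HRV feature triplet.
#' @export
hrv_bands <- function() list(lf = c(0.04, 0.15), hf = c(0.15, 0.40))

#' Enumerate non-overlapping LF/HF band combinations
#'
#' All grid-aligned triples `(lf_lo, split, hf_hi)` with
#' `0 <= lf_lo < split < hf_hi <= f_max`, defining LF = `[lf_lo, split)`
#' and HF = `[split, hf_hi)`. For step 0.01 and `f_max` 1 this is
#' `choose(101, 3)` = 166650 combinations, in lexicographic order.
#'
#' @param step grid step in Hz (default 0.01).
#' @param f_max upper frequency limit in Hz (default 1.0); `f_max/step`
#'   must be integral.
#' @return A data.frame with columns `lf_lo`, `split`, `hf_hi` (Hz) and
#'   the corresponding 1-based edge indices `i`, `j`, `k`, plus attribute
#'   `"edges"` (the grid-edge frequencies).
#' @export
enumerate_combinations <- function(step = 0.01, f_max = 1.0) {
  m <- f_max / step
  if (abs(m - round(m)) > 1e-9)
    stop("`f_max` must be an integer multiple of `step`")
  m <- as.integer(round(m))
  edges <- (0:m) * step
  cmb <- utils::combn(m + 1L, 3L)
  out <- data.frame(lf_lo = edges[cmb[1, ]], split = edges[cmb[2, ]],
                    hf_hi = edges[cmb[3, ]],
                    i = cmb[1, ], j = cmb[2, ], k = cmb[3, ])
  attr(out, "edges") <- edges
  out
}

#' HRV feature triplet per analysis window
#'
#' Band powers in the canonical LF and HF bands plus their ratio, one row
#' per sliding window. Windows with zero HF power get an undefined (NA)
#' ratio and are later dropped pairwise for the ratio feature.
#'
#' @param wp a [window_psds()] result for the HRV signal.
#' @return data.frame with columns `lf`, `hf`, `ratio` and one row per
#'   window.
#' @export
hrv_feature_series <- function(wp) {
  b <- hrv_bands()
  lf <- cum_at_matrix(wp, b$lf[2]) - cum_at_matrix(wp, b$lf[1])
  hf <- cum_at_matrix(wp, b$hf[2]) - cum_at_matrix(wp, b$hf[1])
  ratio <- ifelse(hf > 0, lf / hf, NA_real_)
  data.frame(lf = lf, hf = hf, ratio = ratio)
}

#' Per-window cumulative pupil power at the sweep grid edges
#'
#' Samples each window's cumulative power at every band-grid edge, so the
#' power of any band combination is reconstructed exactly as a difference
#' of two stored values (band-power additivity).
#'
#' @param wp a [window_psds()] result for the pupil signal.
#' @param edges grid-edge frequencies (Hz), e.g.
#'   `attr(enumerate_combinations(), "edges")`.
#' @return Matrix, windows x edges, non-decreasing along each row.
#' @export
pupil_cumpower_matrix <- function(wp, edges) {
  out <- vapply(edges, function(f) cum_at_matrix(wp, f),
                numeric(nrow(wp$cum)))
  colnames(out) <- sprintf("%.2f", edges)
  out
}

# column-wise correlation of the columns of X with vector y, with two-sided
# t-distribution p-values (n - 2 df); columns containing NA are handled by
# pairwise deletion
col_corr <- function(X, y) {
  full <- !anyNA(X) && !anyNA(y)
  if (full) {
    n <- length(y)
    yc <- y - mean(y)
    Xc <- sweep(X, 2, colMeans(X))
    num <- as.vector(crossprod(Xc, yc))
    den <- sqrt(colSums(Xc^2) * sum(yc^2))
    r <- ifelse(den > 0, num / den, NA_real_)
    nv <- rep(n, ncol(X))
  } else {
    r <- numeric(ncol(X)); nv <- integer(ncol(X))
    for (c in seq_len(ncol(X))) {
      ok <- is.finite(X[, c]) & is.finite(y)
      nv[c] <- sum(ok)
      r[c] <- if (nv[c] >= 3 && stats::sd(X[ok, c]) > 0 && stats::sd(y[ok]) > 0)
        stats::cor(X[ok, c], y[ok]) else NA_real_
    }
  }
  r <- pmin(pmax(r, -1), 1)
  tstat <- abs(r) * sqrt((nv - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = nv - 2, lower.tail = FALSE)
  list(r = r, p = p, n = nv)
}

rank_cols <- function(X) apply(X, 2, rank)

# Spearman with pairwise deletion of windows whose ratio is undefined:
# ranks are recomputed inside each complete pair set
col_corr_spearman_pairwise <- function(X, y) {
  r <- numeric(ncol(X)); nv <- integer(ncol(X))
  for (c in seq_len(ncol(X))) {
    ok <- is.finite(X[, c]) & is.finite(y)
    nv[c] <- sum(ok)
    r[c] <- if (nv[c] >= 3) suppressWarnings(
      stats::cor(X[ok, c], y[ok], method = "spearman")) else NA_real_
  }
  r <- pmin(pmax(r, -1), 1)
  tstat <- abs(r) * sqrt((nv - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = nv - 2, lower.tail = FALSE)
  list(r = r, p = p, n = nv)
}

#' Per-run correlation of pupil band features with HRV features
#'
#' For every band combination, correlates the window series of pupil LF
#' power, HF power and LF/HF ratio with the corresponding HRV feature
#' (LF with LF, HF with HF, ratio with ratio), by Pearson (default) or
#' Spearman correlation, with two-sided t-transform p-values on `n - 2`
#' degrees of freedom. Windows with an undefined ratio are dropped
#' pairwise for the ratio feature only.
#'
#' @param pupil_cum matrix from [pupil_cumpower_matrix()] (windows x edges).
#' @param hrv_feat data.frame from [hrv_feature_series()], same windows.
#' @param combos data.frame from [enumerate_combinations()].
#' @param method `"pearson"` or `"spearman"`.
#' @param chunk combos processed per block (memory control).
#' @return data.frame: the combination columns plus `r_lf`, `p_lf`, `r_hf`,
#'   `p_hf`, `r_ratio`, `p_ratio`, `n`.
#' @export
per_run_correlation <- function(pupil_cum, hrv_feat, combos,
                                method = c("pearson", "spearman"),
                                chunk = 4000L) {
  method <- match.arg(method)
  nwin <- nrow(pupil_cum)
  if (nwin != nrow(hrv_feat)) stop("window series are not aligned")
  if (nwin < 3L) stop("need at least 3 windows to correlate")
  nc <- nrow(combos)
  res <- data.frame(combos[, c("lf_lo", "split", "hf_hi")],
                    r_lf = NA_real_, p_lf = NA_real_,
                    r_hf = NA_real_, p_hf = NA_real_,
                    r_ratio = NA_real_, p_ratio = NA_real_,
                    n = nwin)
  y_lf <- hrv_feat$lf; y_hf <- hrv_feat$hf; y_ratio <- hrv_feat$ratio
  if (method == "spearman") {
    y_lf <- rank(y_lf); y_hf <- rank(y_hf)
    if (!anyNA(y_ratio)) y_ratio <- rank(y_ratio)
  }
  for (lo in seq(1L, nc, by = chunk)) {
    hi <- min(lo + chunk - 1L, nc)
    ii <- combos$i[lo:hi]; jj <- combos$j[lo:hi]; kk <- combos$k[lo:hi]
    LF <- pupil_cum[, jj, drop = FALSE] - pupil_cum[, ii, drop = FALSE]
    HF <- pupil_cum[, kk, drop = FALSE] - pupil_cum[, jj, drop = FALSE]
    RATIO <- ifelse(HF > 0, LF / HF, NA_real_)
    if (method == "spearman") {
      LF <- rank_cols(LF); HF <- rank_cols(HF)
      if (!anyNA(RATIO)) RATIO <- rank_cols(RATIO)
    }
    cl <- col_corr(LF, y_lf)
    ch <- col_corr(HF, y_hf)
    cr <- if (method == "spearman" && (anyNA(RATIO) || anyNA(y_ratio)))
      col_corr_spearman_pairwise(RATIO, hrv_feat$ratio) else
      col_corr(RATIO, y_ratio)
    res$r_lf[lo:hi] <- cl$r; res$p_lf[lo:hi] <- cl$p
    res$r_hf[lo:hi] <- ch$r; res$p_hf[lo:hi] <- ch$p
    res$r_ratio[lo:hi] <- cr$r; res$p_ratio[lo:hi] <- cr$p
  }
  res
}
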