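# Singular spectrum analysis: Hankel embedding + SVD + diagonal averaging,
# and the iterative reconstruction loop used to repair artifact-flagged
# samples of the pupil stream.

#' SSA configuration
#'
#' @param window_len embedding dimension L in samples (2 <= L <= N/2). The
#'   pipeline default is 30 s at the analysis rate (240 samples at 8 Hz).
#' @param n_components number of leading components used for reconstruction,
#'   or `NULL` to pick the smallest count explaining at least
#'   `energy_frac` of the squared-singular-value energy.
#' @param energy_frac energy fraction for automatic component selection
#'   (default 0.9).
#' @param max_iter maximum reconstruction iterations (default 20).
#' @param tol convergence threshold: maximum change at flagged positions,
#'   relative to the RMS of the series (default 1e-3).
#' @return A list of class `ssa_config`.
#' @export
ssa_config <- function(window_len = 240, n_components = NULL,
                       energy_frac = 0.9, max_iter = 20, tol = 1e-3) {
  stopifnot(window_len >= 2, max_iter >= 1, tol >= 0,
            energy_frac > 0, energy_frac <= 1)
  if (!is.null(n_components) && n_components < 1)
    stop("`n_components` must be >= 1")
  structure(list(window_len = as.integer(window_len),
                 n_components = n_components, energy_frac = energy_frac,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "ssa_config")
}

# Hankel trajectory matrix (L x K), K = N - L + 1
ssa_trajectory <- function(x, L) {
  N <- length(x)
  K <- N - L + 1
  matrix(x[outer(seq_len(L), seq_len(K) - 1L, `+`)], nrow = L)
}

# diagonal averaging of the rank-1 outer product d * u v^T back to a series;
# conv(u, v) summed over anti-diagonals divided by anti-diagonal lengths
ssa_diag_average <- function(u, v) {
  s <- stats::convolve(u, rev(v), type = "open")
  L <- length(u); K <- length(v); N <- L + K - 1
  counts <- pmin(seq_len(N), L, K, N - seq_len(N) + 1)
  s / counts
}

#' SSA decomposition of a series
#'
#' Embeds the series in a Hankel trajectory matrix of window length L,
#' takes its SVD, and reconstructs one elementary series per singular
#' triple by diagonal averaging. Components are ordered by decreasing
#' singular value and sum exactly to the input.
#'
#' @param x fully valid numeric series.
#' @param window_len embedding dimension L, `2 <= L <= length(x)/2`.
#' @return A matrix `length(x) x L` whose columns are the elementary
#'   component series, with attribute `"d"` holding the singular values.
#' @export
ssa_decompose <- function(x, window_len) {
  x <- as.numeric(x)
  N <- length(x)
  L <- as.integer(window_len)
  if (L < 2L || L > N / 2) stop("`window_len` must satisfy 2 <= L <= N/2")
  if (any(!is.finite(x))) stop("series must be fully valid (finite)")
  sv <- svd(ssa_trajectory(x, L))
  comps <- vapply(seq_len(L), function(i) {
    sv$d[i] * ssa_diag_average(sv$u[, i], sv$v[, i])
  }, numeric(N))
  attr(comps, "d") <- sv$d
  comps
}

# rank-m SSA reconstruction (internal fast path; no per-component matrices)
ssa_reconstruct <- function(x, L, n_components = NULL, energy_frac = 0.9) {
  sv <- svd(ssa_trajectory(x, L))
  m <- if (is.null(n_components)) {
    e <- cumsum(sv$d^2) / sum(sv$d^2)
    which(e >= energy_frac)[1]
  } else min(n_components, L)
  rec <- numeric(length(x))
  for (i in seq_len(m)) {
    rec <- rec + sv$d[i] * ssa_diag_average(sv$u[, i], sv$v[, i])
  }
  attr(rec, "n_components") <- m
  rec
}

#' Iterative SSA repair of artifact-flagged samples
#'
#' Alternates SSA reconstruction from the leading components with
#' replacement of the flagged samples by the reconstruction, until the
#' largest change at flagged positions (relative to the series RMS) falls
#' below `cfg$tol` or `cfg$max_iter` is reached. Unflagged samples keep
#' their original values in the output; only flagged positions are smoothed.
#'
#' @param sig a fully valid [sampled_signal()] (gaps already filled).
#' @param flags logical vector marking artifact positions, same length.
#' @param cfg an [ssa_config()].
#' @return A `sampled_signal` with repaired values. Attribute `"report"`
#'   lists `iterations`, `converged` and the component count used. A
#'   warning (not an error) is raised on non-convergence.
#' @export
iterative_ssa_clean <- function(sig, flags, cfg = ssa_config()) {
  stopifnot(inherits(sig, "sampled_signal"), inherits(cfg, "ssa_config"))
  flags <- as.logical(flags)
  if (length(flags) != length(sig$values))
    stop("`flags` must match the signal length")
  x <- sig$values
  N <- length(x)
  L <- cfg$window_len
  if (L < 2L || L > N / 2) stop("`window_len` must satisfy 2 <= L <= N/2")
  if (!any(flags)) {
    out <- sig
    attr(out, "report") <- list(iterations = 0L, converged = TRUE,
                                n_components = 0L, n_flagged = 0L)
    return(out)
  }
  scale <- sqrt(mean(x^2)) + .Machine$double.eps
  converged <- FALSE
  it <- 0L
  m_used <- NA_integer_
  while (it < cfg$max_iter) {
    it <- it + 1L
    rec <- ssa_reconstruct(x, L, cfg$n_components, cfg$energy_frac)
    m_used <- attr(rec, "n_components")
    delta <- max(abs(rec[flags] - x[flags])) / scale
    x[flags] <- rec[flags]
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("iterative SSA did not converge in %d iterations", it))
  out <- sampled_signal(x, sig$fs, sig$t0, rep(TRUE, N))
  attr(out, "report") <- list(iterations = it, converged = converged,
                              n_components = m_used,
                              n_flagged = sum(flags))
  out
}
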