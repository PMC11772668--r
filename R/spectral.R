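# Burg autoregressive spectral estimation on sliding windows, band-power
# integration, and cumulative-power diagnostics.
#
# Conventions (recorded in the methods vignette): AR order 16 by default;
# windows are mean-subtracted before fitting; the PSD is one-sided (power
# doubled for 0 < f < Nyquist) on a uniform 2049-point grid over
# [0, fs/2]; band edges are treated as half-open [lo, hi), which is
# immaterial for the continuous integral but fixes the partition.

#' Burg autoregressive model fit
#'
#' Fits an AR(p) model by Burg's method (forward-backward prediction error
#' minimization with a Levinson-type recursion, via [stats::ar.burg()]).
#' Coefficients are stored in denominator convention: the AR polynomial is
#' `1 + sum(a_k z^-k)`, so a process `x_t = 0.7 x_{t-1} + e_t` yields
#' `a_1` near -0.7.
#'
#' @param x numeric series, length > 2 * order, non-constant.
#' @param order model order p (default 16).
#' @return An object of class `ar_model`: list with `order`,
#'   `coefficients` (denominator convention), `reflection` (partial
#'   autocorrelations, all inside (-1, 1)), `noise_variance`.
#' @export
burg_fit <- function(x, order = 16) {
  x <- as.numeric(x)
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1")
  if (length(x) <= 2L * order)
    stop("series length must exceed 2 * order")
  if (any(!is.finite(x))) stop("series must be finite")
  if (stats::sd(x) == 0)
    stop("constant series: Burg prediction error is zero")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  structure(list(order = order,
                 coefficients = -as.numeric(fit$ar),
                 reflection = as.numeric(fit$partialacf),
                 noise_variance = fit$var.pred),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> order %d, noise variance %.4g\n",
              x$order, x$noise_variance))
  invisible(x)
}

# complex frequency-response denominator basis for a grid; reusable across
# windows sharing (freqs, fs, order)
ar_basis <- function(freqs, fs, order) {
  exp(-1i * 2 * pi * outer(freqs, seq_len(order)) / fs)
}

ar_density <- function(coefficients, noise_variance, freqs, fs, basis = NULL) {
  p <- length(coefficients)
  if (is.null(basis)) basis <- ar_basis(freqs, fs, p)
  denom <- Mod(1 + as.vector(basis %*% coefficients))^2
  scale <- ifelse(freqs > 0 & freqs < fs / 2, 2, 1)  # one-sided doubling
  scale * noise_variance / (fs * denom)
}

cumtrapz_vec <- function(f, y) c(0, cumsum(diff(f) * (y[-1] + y[-length(y)]) / 2))

#' Power spectral density of an AR model
#'
#' Evaluates the one-sided AR spectrum
#' `S(f) = c(f) * sigma^2 / (fs * |1 + sum a_k exp(-i 2 pi k f / fs)|^2)`
#' (with `c(f) = 2` for `0 < f < fs/2` and 1 at the endpoints) on a uniform
#' grid over `[0, fs/2]`, together with the trapezoidally integrated
#' cumulative power.
#'
#' @param model an [burg_fit()] result.
#' @param fs sampling rate in Hz.
#' @param n_grid number of grid points (default 2049).
#' @return An object of class `psd_estimate`: list with `freqs`, `density`,
#'   `cum_power` (with `cum_power[1] = 0` and last element the total power).
#' @export
ar_psd <- function(model, fs, n_grid = 2049) {
  stopifnot(inherits(model, "ar_model"))
  if (n_grid < 2L) stop("`n_grid` must be >= 2")
  if (length(model$coefficients)) {
    roots <- polyroot(rev(c(1, model$coefficients)))
    if (any(Mod(roots) >= 1))
      stop("unstable AR model (characteristic root on/outside unit circle)")
  }
  freqs <- seq(0, fs / 2, length.out = n_grid)
  dens <- ar_density(model$coefficients, model$noise_variance, freqs, fs)
  structure(list(freqs = freqs, density = dens,
                 cum_power = cumtrapz_vec(freqs, dens)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d points over [0, %g] Hz, total power %.4g\n",
              length(x$freqs), max(x$freqs), x$cum_power[length(x$cum_power)]))
  invisible(x)
}

# linear interpolation of the cumulative power at arbitrary frequencies
cum_power_at <- function(psd, f) {
  stats::approx(psd$freqs, psd$cum_power, xout = f, rule = 2)$y
}

#' Band power from a PSD estimate
#'
#' Integrated power over the half-open band `[f_lo, f_hi)`, computed as the
#' difference of the cumulative power at the edges (linear interpolation
#' between grid points). By construction adjacent bands partition power.
#'
#' @param psd a [ar_psd()] result.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= fs/2`.
#' @return Power in signal units squared.
#' @export
band_power <- function(psd, f_lo, f_hi) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (!(f_lo >= 0 && f_lo < f_hi))
    stop("band edges must satisfy 0 <= f_lo < f_hi")
  if (f_hi > max(psd$freqs) + 1e-12)
    stop("f_hi exceeds the PSD frequency range")
  cum_power_at(psd, f_hi) - cum_power_at(psd, f_lo)
}

#' Frequency below which a fraction of total power lies
#'
#' Smallest grid frequency at which the cumulative power reaches
#' `q * total`; used for the cumulative-power percentile diagnostics
#' (90/95/97.5/99%).
#'
#' @param psd a [ar_psd()] result (or any `psd_estimate`).
#' @param q fraction in (0, 1).
#' @return Frequency in Hz.
#' @export
power_percentile_freq <- function(psd, q) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (!(q > 0 && q < 1)) stop("`q` must be in (0, 1)")
  total <- psd$cum_power[length(psd$cum_power)]
  psd$freqs[which(psd$cum_power >= q * total)[1]]
}

#' Sliding analysis windows
#'
#' Cuts a signal into `win`-second windows advanced by `step` seconds; the
#' count is `floor((span - win)/step) + 1` where `span` is the signal
#' duration. Each window holds exactly `win * fs` samples.
#'
#' @param sig a [sampled_signal()] spanning at least `win` seconds.
#' @param win window length in seconds (default 180).
#' @param step window step in seconds (default 1).
#' @return An object of class `analysis_windows`: list with `values`
#'   (matrix, one row per window), `starts` (window start times, s), `fs`,
#'   `win`, `step`.
#' @export
sliding_windows <- function(sig, win = 180, step = 1) {
  stopifnot(inherits(sig, "sampled_signal"))
  span <- signal_span(sig)
  if (span < win) stop("signal span is shorter than the window length")
  nw <- floor((span - win) / step) + 1
  wlen <- round(win * sig$fs)
  slen <- round(step * sig$fs)
  idx0 <- (seq_len(nw) - 1L) * slen
  vals <- matrix(sig$values[outer(idx0, seq_len(wlen), `+`)], nrow = nw)
  structure(list(values = vals, starts = sig$t0 + idx0 / sig$fs,
                 fs = sig$fs, win = win, step = step),
            class = "analysis_windows")
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat(sprintf("<analysis_windows> %d windows of %g s (step %g s) @ %g Hz\n",
              nrow(x$values), x$win, x$step, x$fs))
  invisible(x)
}

#' Burg PSDs for every sliding window
#'
#' Mean-subtracts each window, fits an AR model of the given order by
#' Burg's method, and evaluates the one-sided spectrum on a shared grid.
#'
#' @param wins an [sliding_windows()] result.
#' @param order AR order (default 16).
#' @param n_grid PSD grid size over `[0, fs/2]` (default 2049).
#' @return A list with `freqs`, `density` (windows x grid matrix), `cum`
#'   (cumulative power, windows x grid), `starts`, `fs`, `order`.
#' @export
window_psds <- function(wins, order = 16, n_grid = 2049) {
  stopifnot(inherits(wins, "analysis_windows"))
  freqs <- seq(0, wins$fs / 2, length.out = n_grid)
  basis <- ar_basis(freqs, wins$fs, order)
  nw <- nrow(wins$values)
  dens <- matrix(NA_real_, nw, n_grid)
  for (i in seq_len(nw)) {
    w <- wins$values[i, ]
    w <- w - mean(w)
    fit <- stats::ar.burg(w, aic = FALSE, order.max = order, demean = FALSE)
    dens[i, ] <- ar_density(-as.numeric(fit$ar), fit$var.pred,
                            freqs, wins$fs, basis)
  }
  df <- diff(freqs)
  cum <- cbind(0, t(apply((dens[, -1, drop = FALSE] +
                           dens[, -n_grid, drop = FALSE]) / 2, 1,
                          function(r) cumsum(df * r))))
  list(freqs = freqs, density = dens, cum = cum,
       starts = wins$starts, fs = wins$fs, order = order)
}

# vectorized cumulative power of every window at one frequency
cum_at_matrix <- function(wp, f) {
  n <- length(wp$freqs)
  pos <- (f - wp$freqs[1]) / (wp$freqs[2] - wp$freqs[1])
  lo <- pmin(pmax(floor(pos), 0), n - 2) + 1
  frac <- pos - (lo - 1)
  wp$cum[, lo] * (1 - frac) + wp$cum[, lo + 1] * frac
}
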