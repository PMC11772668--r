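# Zero-phase filtering stages shared by the HRV and pupil pipelines.
# Ordinary cutoffs go through signal::butter + signal::filtfilt. The drift
# high-pass is special-cased: at 4e-4 Hz and fs = 8 the impulse response of
# any IIR realization spans several hundred seconds, so forward-backward
# filtering with padding distorts records of typical run length. It is
# applied instead as a linear detrend followed by multiplication of the FFT
# by the squared magnitude of the same 2nd-order Butterworth high-pass --
# the exact zero-phase equivalent of the forward-backward cascade, free of
# edge transients.

# zero-phase IIR filtering with odd-reflection padding and steady-state
# initial conditions (the padding/initialization scheme of scipy's
# filtfilt); signal::filtfilt starts its passes from zero state, which
# leaves large step transients at the record edges
filtfilt_ss <- function(bf, x) {
  b <- bf$b; a <- bf$a
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- length(x)
  npad <- min(3L * nfilt, n - 1L)
  ext <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  dc_gain <- sum(b) / sum(a)
  pass1 <- function(z) {
    y0 <- z[1] * dc_gain
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], nfilt - 1),
                              init.y = rep(y0, nfilt - 1)))
  }
  y <- rev(pass1(rev(pass1(ext))))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase), as used to
#' restrict the resampled HRV series to its informative sub-1 Hz content.
#'
#' @param sig a [sampled_signal()].
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist rate.
#' @param order filter order (default 4).
#' @return A `sampled_signal` of the same length, rate and mask.
#' @export
lowpass <- function(sig, cutoff, order = 4) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (cutoff >= sig$fs / 2)
    stop("`cutoff` must be below the Nyquist frequency fs/2")
  if (cutoff <= 0) stop("`cutoff` must be positive")
  bf <- signal::butter(order, cutoff / (sig$fs / 2), type = "low")
  sampled_signal(filtfilt_ss(bf, sig$values), sig$fs, sig$t0, sig$valid)
}

#' Zero-phase high-pass filter for slow-drift removal
#'
#' Removes content slower than `cutoff` (default 4e-4 Hz, i.e. drifts on the
#' scale of tens of minutes) with the zero-phase response of a 2nd-order
#' Butterworth high-pass. Realized as a linear detrend plus frequency-domain
#' application of the squared filter magnitude, which is numerically exact at
#' cutoffs far below the resolvable frequency of the record (see the methods
#' vignette for why a time-domain forward-backward pass is unusable there).
#'
#' @param sig a [sampled_signal()].
#' @param cutoff high-pass cutoff in Hz (default 4e-4).
#' @param order analog prototype order of the Butterworth magnitude (default 2).
#' @return A `sampled_signal` of the same length, rate and mask.
#' @export
highpass <- function(sig, cutoff = 4e-4, order = 2) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (cutoff >= sig$fs / 2)
    stop("`cutoff` must be below the Nyquist frequency fs/2")
  if (cutoff <= 0) stop("`cutoff` must be positive")
  x <- sig$values
  n <- length(x)
  if (n < 4L) stop("signal too short to high-pass filter")
  # linear detrend: removes the component the periodic FFT cannot represent
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  xd <- fit$residuals
  f <- seq(0, n - 1) * sig$fs / n
  f <- pmin(f, sig$fs - f)            # two-sided frequency axis
  u <- (f / cutoff)^(2 * order)
  gain <- u / (1 + u)                 # |H|^2 of Butterworth high-pass
  y <- Re(stats::fft(stats::fft(xd) * gain, inverse = TRUE)) / n
  sampled_signal(y, sig$fs, sig$t0, sig$valid)
}

#' Anti-aliased downsampling
#'
#' Low-pass filters at 0.8 of the target Nyquist frequency (4th-order
#' Butterworth, zero phase) and then resamples onto the uniform target grid
#' by linear interpolation of the filtered series; used to bring the
#' 500 Hz eye-tracker stream down to the 8 Hz analysis rate.
#'
#' @param sig a fully valid [sampled_signal()].
#' @param target_fs target sampling rate in Hz; must be below `sig$fs`.
#' @return A `sampled_signal` at `target_fs` starting at `sig$t0`.
#' @export
downsample <- function(sig, target_fs) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (target_fs >= sig$fs)
    stop("`target_fs` must be below the input sampling rate")
  bf <- signal::butter(4, (0.8 * target_fs / 2) / (sig$fs / 2), type = "low")
  y <- filtfilt_ss(bf, sig$values)
  tin <- signal_times(sig)
  n_out <- floor(signal_span(sig) * target_fs) + 1
  tout <- sig$t0 + (seq_len(n_out) - 1) / target_fs
  v <- stats::approx(tin, y, xout = tout)$y
  sampled_signal(v, target_fs, sig$t0)
}
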