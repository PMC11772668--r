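# HRV preprocessing: beat annotations -> clean uniform 8 Hz tachogram.
# Stages: RR computation, Tukey boxplot outlier removal, linear
# interpolation onto a uniform grid, 1 Hz zero-phase low-pass.

#' RR series from beat times
#'
#' @param beat_times strictly increasing R-peak times in seconds (>= 3).
#' @return An [rr_series()].
#' @export
rr_from_peaks <- function(beat_times) rr_series(beat_times)

#' Tukey boxplot outlier filter
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` (classical boxplot
#' fences). With zero IQR (constant data) nothing is flagged, so constant
#' segments are never deleted.
#'
#' @param x numeric vector (>= 4 values).
#' @param k fence multiplier (default 1.5).
#' @return A list with `kept` (surviving values), `removed` (integer indices
#'   of removed values in `x`) and `keep` (logical mask over `x`).
#' @export
boxplot_outlier_filter <- function(x, k = 1.5) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("boxplot outlier filter needs at least 4 values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  keep <- x >= q[1] - k * iqr & x <= q[2] + k * iqr
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("boxplot filter removed every value (degenerate input)")
  list(kept = x[keep], removed = which(!keep), keep = keep)
}

#' Uniform resampling of a tachogram by linear interpolation
#'
#' Interpolates the (timestamp, interval) pairs of an RR series linearly
#' onto a uniform grid at `fs`, the standard step before spectral analysis
#' of HRV. Intervals removed as outliers are bridged by the interpolant.
#'
#' @param rr an [rr_series()].
#' @param fs target sampling rate in Hz (default 8).
#' @param keep optional logical mask over `rr$intervals` (from
#'   [boxplot_outlier_filter()]); defaults to all kept.
#' @return A [sampled_signal()] of RR values in ms at `fs`, starting at the
#'   timestamp of the first surviving interval; length
#'   `floor(span * fs) + 1`.
#' @export
uniform_resample_linear <- function(rr, fs = 8, keep = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(keep)) keep <- rep(TRUE, length(rr$intervals))
  tt <- rr$beat_times[-1][keep]       # interval timestamped at terminating beat
  vv <- rr$intervals[keep]
  if (length(vv) < 2L) stop("fewer than 2 surviving intervals")
  span <- tt[length(tt)] - tt[1]
  n <- floor(span * fs) + 1
  if (n < 2L) stop("tachogram span too short for the requested rate")
  grid <- tt[1] + (seq_len(n) - 1) / fs
  sampled_signal(stats::approx(tt, vv, xout = grid)$y, fs, tt[1])
}

#' Full HRV preprocessing chain
#'
#' Beat times -> RR intervals -> boxplot outlier removal -> linear
#' interpolation and resampling to 8 Hz -> zero-phase 1 Hz low-pass.
#'
#' @param beats either an [rr_series()] or a numeric vector of beat times (s).
#' @param fs analysis sampling rate (default 8 Hz).
#' @param lowpass_cutoff low-pass cutoff in Hz (default 1).
#' @param k boxplot fence multiplier (default 1.5).
#' @return A [sampled_signal()] of clean RR values (ms). Attribute
#'   `"report"` carries counts of removed outliers.
#' @export
preprocess_hrv <- function(beats, fs = 8, lowpass_cutoff = 1, k = 1.5) {
  rr <- if (inherits(beats, "rr_series")) beats else rr_from_peaks(beats)
  flt <- boxplot_outlier_filter(rr$intervals, k = k)
  sig <- uniform_resample_linear(rr, fs = fs, keep = flt$keep)
  out <- lowpass(sig, lowpass_cutoff)
  attr(out, "report") <- list(n_beats = length(rr$beat_times),
                              n_outliers_removed = length(flt$removed),
                              n_samples = length(out$values))
  out
}
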