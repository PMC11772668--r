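#' Uniformly sampled signal
#'
#' The common currency of the preprocessing stages: a real-valued series
#' sampled at a fixed rate, with a start time and a per-sample validity mask
#' (used by the pupil stream to flag device-reported invalid samples and,
#' later, samples removed as outliers).
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param valid logical vector of the same length as `values`; `TRUE` marks a
#'   usable sample. Defaults to all valid.
#' @return An object of class `sampled_signal`: a list with elements
#'   `values`, `fs`, `t0`, `valid`.
#' @export
sampled_signal <- function(values, fs, t0 = 0, valid = NULL) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(valid)) valid <- rep(TRUE, length(values))
  valid <- as.logical(valid)
  if (length(valid) != length(values))
    stop("`valid` must have the same length as `values`")
  structure(list(values = values, fs = fs, t0 = as.numeric(t0), valid = valid),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz, t0 = %g s, %d invalid\n",
              length(x$values), x$fs, x$t0, sum(!x$valid)))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Sample times of a sampled signal
#'
#' @param x a `sampled_signal`.
#' @return numeric vector of times in seconds, `t0 + (0:(n-1))/fs`.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Time span of a sampled signal in seconds
#'
#' @param x a `sampled_signal`.
#' @return `(n - 1) / fs`, the time between first and last sample.
#' @export
signal_span <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  (length(x$values) - 1) / x$fs
}

#' RR-interval series (tachogram)
#'
#' Beat times with the derived inter-beat intervals in milliseconds. The
#' interval `intervals[i]` is assigned the timestamp of its terminating beat,
#' `beat_times[i + 1]`.
#'
#' @param beat_times strictly increasing beat times in seconds (>= 3 beats).
#' @return An object of class `rr_series` with elements `beat_times` (s) and
#'   `intervals` (ms, one fewer than the number of beats).
#' @export
rr_series <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 3L)
    stop("at least 3 beats are required to form an RR series")
  if (any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing")
  structure(list(beat_times = beat_times,
                 intervals = diff(beat_times) * 1000),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s, mean RR %.1f ms\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$intervals)))
  invisible(x)
}
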