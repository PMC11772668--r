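# Pupillography preprocessing chain, in fixed order:
# invalid-sample masking with +/-100 ms margins -> boxplot outlier removal
# -> shape-preserving cubic gap filling -> anti-aliased downsampling to
# 8 Hz -> iterative SSA artifact repair -> 4e-4 Hz drift high-pass.

#' Expand the invalid mask by a time margin
#'
#' Marks every sample within `margin` milliseconds of an invalid stretch as
#' invalid itself, so samples just before a blink onset and just after its
#' offset (where the diameter estimate is already distorted) are discarded
#' too. Nearby stretches closer than twice the margin merge.
#'
#' @param sig a [sampled_signal()].
#' @param margin margin in milliseconds (default 100).
#' @return A `sampled_signal` with the widened mask.
#' @export
mask_invalid_with_margin <- function(sig, margin = 100) {
  stopifnot(inherits(sig, "sampled_signal"))
  if (margin < 0) stop("`margin` must be >= 0")
  bad <- !sig$valid
  if (!any(bad)) return(sig)
  w <- ceiling(margin / 1000 * sig$fs)
  n <- length(bad)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  newbad <- bad
  for (i in which(r$values)) {
    lo <- max(1L, starts[i] - w)
    hi <- min(n, ends[i] + w)
    newbad[lo:hi] <- TRUE
  }
  sampled_signal(sig$values, sig$fs, sig$t0, !newbad)
}

#' Fill invalid samples by shape-preserving piecewise cubic interpolation
#'
#' Replaces invalid samples with a monotonicity-preserving piecewise cubic
#' (Fritsch-Carlson) interpolant of the valid neighbours; the interpolant
#' reproduces linear trends exactly and never overshoots beyond the
#' enclosing valid values on monotone data. Leading and trailing invalid
#' samples cannot be interpolated and must be trimmed first (see
#' [trim_invalid_edges()]).
#'
#' @param sig a [sampled_signal()] whose first and last samples are valid.
#' @return A fully valid `sampled_signal`.
#' @export
fill_gaps_shape_preserving_cubic <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  ok <- sig$valid
  if (sum(ok) < 2L) stop("fewer than 2 valid samples; cannot interpolate")
  if (all(ok)) return(sig)
  if (!ok[1] || !ok[length(ok)])
    stop("leading/trailing invalid samples must be trimmed before filling")
  tt <- signal_times(sig)
  f <- stats::splinefun(tt[ok], sig$values[ok], method = "monoH.FC")
  v <- sig$values
  v[!ok] <- f(tt[!ok])
  sampled_signal(v, sig$fs, sig$t0)
}

#' Trim leading and trailing invalid samples
#'
#' @param sig a [sampled_signal()].
#' @return The signal restricted to the span between its first and last
#'   valid samples (with `t0` advanced accordingly).
#' @export
trim_invalid_edges <- function(sig) {
  stopifnot(inherits(sig, "sampled_signal"))
  ok <- which(sig$valid)
  if (length(ok) < 2L) stop("fewer than 2 valid samples")
  i0 <- ok[1]; i1 <- ok[length(ok)]
  sampled_signal(sig$values[i0:i1], sig$fs,
                 sig$t0 + (i0 - 1) / sig$fs, sig$valid[i0:i1])
}

# map native-rate artifact flags onto the downsampled grid: a target sample
# is flagged if any flagged native sample lies within half a target period
map_flags_to_grid <- function(flag_times, t0, fs_out, n_out) {
  flagged <- rep(FALSE, n_out)
  if (length(flag_times) == 0L) return(flagged)
  idx <- round((flag_times - t0) * fs_out) + 1
  idx <- idx[idx >= 1 & idx <= n_out]
  flagged[idx] <- TRUE
  flagged
}

#' Full pupillography preprocessing chain
#'
#' Applies, in order: invalid-sample masking with margins, boxplot outlier
#' removal (removed samples are added to the invalid mask), edge trimming,
#' shape-preserving cubic gap filling, anti-aliased downsampling to the
#' analysis rate, iterative SSA repair at the artifact-flagged positions
#' (the union of masked and outlier samples mapped to the analysis grid),
#' and the slow-drift high-pass.
#'
#' @param sig raw pupil-diameter [sampled_signal()] with device validity mask.
#' @param margin invalid-mask margin in ms (default 100).
#' @param k boxplot fence multiplier (default 1.5).
#' @param target_fs analysis rate in Hz (default 8).
#' @param ssa an [ssa_config()]; its `window_len` defaults to 30 s at
#'   `target_fs`.
#' @param hp_cutoff drift high-pass cutoff in Hz (default 4e-4).
#' @return A clean `sampled_signal` at `target_fs`. Attribute `"report"`
#'   carries per-stage counters (masked, removed, filled, SSA iterations).
#' @export
preprocess_pupil <- function(sig, margin = 100, k = 1.5, target_fs = 8,
                             ssa = ssa_config(window_len = 30 * target_fs),
                             hp_cutoff = 4e-4) {
  stopifnot(inherits(sig, "sampled_signal"))
  n_invalid_raw <- sum(!sig$valid)
  sig <- mask_invalid_with_margin(sig, margin)
  n_masked <- sum(!sig$valid)
  # outlier detection on the valid samples only
  flt <- boxplot_outlier_filter(sig$values[sig$valid], k = k)
  out_idx <- which(sig$valid)[flt$removed]
  valid2 <- sig$valid
  valid2[out_idx] <- FALSE
  sig <- sampled_signal(sig$values, sig$fs, sig$t0, valid2)
  sig <- trim_invalid_edges(sig)
  flag_times <- signal_times(sig)[!sig$valid]
  filled <- fill_gaps_shape_preserving_cubic(sig)
  ds <- downsample(filled, target_fs)
  flags <- map_flags_to_grid(flag_times, ds$t0, target_fs, length(ds$values))
  cleaned <- iterative_ssa_clean(ds, flags, ssa)
  ssa_report <- attr(cleaned, "report")
  out <- highpass(cleaned, hp_cutoff)
  attr(out, "report") <- list(
    n_samples_in = length(sig$values),
    n_invalid_raw = n_invalid_raw,
    n_masked = n_masked,
    n_outliers_removed = length(out_idx),
    n_filled = sum(!sig$valid),
    n_flagged_8hz = ssa_report$n_flagged,
    ssa_iterations = ssa_report$iterations,
    ssa_converged = ssa_report$converged,
    n_samples_out = length(out$values))
  out
}
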