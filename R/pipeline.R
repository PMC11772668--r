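# End-to-end orchestration: preprocessing -> windowed Burg spectra ->
# band sweep -> group aggregation and ranking, plus the cumulative-power
# diagnostics and the cognitive-load condition contrast.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain with the
#' defaults used throughout: 8 Hz analysis rate, 180 s / 1 s sliding
#' windows, AR order 16, 0.01 Hz sweep grid over 0-1 Hz, Pearson
#' correlation, cluster permutation at alpha 0.05.
#'
#' @param fs analysis sampling rate (Hz).
#' @param win,step sliding-window length and step (s).
#' @param order Burg AR model order.
#' @param n_grid PSD grid size over `[0, fs/2]`.
#' @param band_step sweep grid step (Hz).
#' @param f_max sweep upper limit (Hz).
#' @param method correlation method, `"pearson"` or `"spearman"`.
#' @param hrv_lowpass HRV low-pass cutoff (Hz).
#' @param pupil_margin invalid-mask margin (ms).
#' @param boxplot_k Tukey fence multiplier.
#' @param hp_cutoff pupil drift high-pass cutoff (Hz).
#' @param ssa an [ssa_config()].
#' @param cluster a [cluster_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 8, win = 180, step = 1, order = 16,
                            n_grid = 2049, band_step = 0.01, f_max = 1.0,
                            method = "pearson", hrv_lowpass = 1,
                            pupil_margin = 100, boxplot_k = 1.5,
                            hp_cutoff = 4e-4,
                            ssa = ssa_config(window_len = 30 * fs),
                            cluster = cluster_config()) {
  stopifnot(fs > 0, win > 0, step > 0, order >= 1, n_grid >= 2,
            band_step > 0, f_max > band_step,
            method %in% c("pearson", "spearman"),
            hrv_lowpass < fs / 2, pupil_margin >= 0, boxplot_k > 0,
            hp_cutoff > 0, inherits(ssa, "ssa_config"),
            inherits(cluster, "cluster_config"))
  structure(as.list(environment()), class = "pipeline_config")
}

# crop two sampled signals to their overlapping span and equal length
align_signals <- function(a, b) {
  t0 <- max(a$t0, b$t0)
  t1 <- min(a$t0 + signal_span(a), b$t0 + signal_span(b))
  if (t1 - t0 <= 0) stop("signals do not overlap in time")
  crop <- function(s) {
    i0 <- which(signal_times(s) >= t0 - 1e-9)[1]
    i1 <- max(which(signal_times(s) <= t1 + 1e-9))
    sampled_signal(s$values[i0:i1], s$fs, s$t0 + (i0 - 1) / s$fs,
                   s$valid[i0:i1])
  }
  a <- crop(a); b <- crop(b)
  n <- min(length(a$values), length(b$values))
  list(sampled_signal(a$values[1:n], a$fs, a$t0, a$valid[1:n]),
       sampled_signal(b$values[1:n], b$fs, b$t0, b$valid[1:n]))
}

#' Windowed spectral features for one run
#'
#' Aligns the clean HRV and pupil signals to their common span, cuts both
#' into the same sliding windows, estimates Burg PSDs and returns the HRV
#' feature triplets plus the pupil cumulative-power matrix at the sweep
#' grid edges.
#'
#' @param hrv_sig,pupil_sig clean [sampled_signal()]s at the analysis rate.
#' @param config a [pipeline_config()].
#' @param edges sweep grid edges; defaults to the grid implied by `config`.
#' @return list with `hrv_feat`, `pupil_cum`, `n_windows`, `starts`, and
#'   the two `window_psds` results (`hrv_wp`, `pupil_wp`).
#' @export
run_features <- function(hrv_sig, pupil_sig, config = pipeline_config(),
                         edges = NULL) {
  if (is.null(edges))
    edges <- seq(0, config$f_max, by = config$band_step)
  al <- align_signals(hrv_sig, pupil_sig)
  hw <- sliding_windows(al[[1]], config$win, config$step)
  pw <- sliding_windows(al[[2]], config$win, config$step)
  hrv_wp <- window_psds(hw, config$order, config$n_grid)
  pupil_wp <- window_psds(pw, config$order, config$n_grid)
  list(hrv_feat = hrv_feature_series(hrv_wp),
       pupil_cum = pupil_cumpower_matrix(pupil_wp, edges),
       n_windows = nrow(hw$values), starts = hw$starts,
       hrv_wp = hrv_wp, pupil_wp = pupil_wp)
}

#' Run the full similarity analysis on a cohort
#'
#' For every run: HRV and pupil preprocessing, windowed Burg spectra, the
#' band sweep and per-run correlations; then group aggregation with
#' cluster-permutation correction, geometric-mean ranking and the
#' literature-band comparison. Runs failing preprocessing are skipped with
#' a logged reason; the pipeline fails only if fewer than two runs survive.
#'
#' @param runs list of runs; each element needs `rr` (an [rr_series()] or
#'   beat-time vector) and `pupil` (a [sampled_signal()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the group table, top-10
#'   table, literature comparison and a provenance JSON are written there.
#' @param literature_combos band triples for [evaluate_named_combos()];
#'   combos not on the sweep grid are skipped with a note.
#' @return list with `group` (full group table), `top` (top-10), `named`
#'   (literature rows), `per_run` (per-run sweep tables), `reports`
#'   (per-run cleaning reports), `combos`, `config`.
#' @export
run_pipeline <- function(runs, config = pipeline_config(), out_dir = NULL,
                         literature_combos = list(c(0.04, 0.15, 0.40),
                                                  c(0.05, 0.15, 0.45))) {
  if (length(runs) < 2L) stop("need at least 2 runs")
  combos <- enumerate_combinations(config$band_step, config$f_max)
  edges <- attr(combos, "edges")
  # literature combinations may sit off the sweep grid (e.g. 0.15 Hz on a
  # 0.02 Hz grid); their edges are appended to the cumulative-power edge
  # set so their features are computed in the same pass
  lit <- literature_combos
  all_edges <- edges
  lit_combos <- NULL
  if (length(lit)) {
    fmatch <- function(f) {
      i <- which(abs(all_edges - f) < 1e-9)[1]
      if (is.na(i)) {
        all_edges <<- c(all_edges, f)
        i <- length(all_edges)
      }
      i
    }
    lit_combos <- do.call(rbind, lapply(lit, function(cb) {
      data.frame(lf_lo = cb[1], split = cb[2], hf_hi = cb[3],
                 i = fmatch(cb[1]), j = fmatch(cb[2]), k = fmatch(cb[3]))
    }))
  }
  combos_all <- rbind(combos[, c("lf_lo", "split", "hf_hi", "i", "j", "k")],
                      lit_combos)
  per_run <- list(); per_run_lit <- list(); reports <- list()
  for (i in seq_along(runs)) {
    res <- tryCatch({
      hrv <- preprocess_hrv(runs[[i]]$rr, fs = config$fs,
                            lowpass_cutoff = config$hrv_lowpass,
                            k = config$boxplot_k)
      pup <- preprocess_pupil(runs[[i]]$pupil, margin = config$pupil_margin,
                              k = config$boxplot_k, target_fs = config$fs,
                              ssa = config$ssa, hp_cutoff = config$hp_cutoff)
      feats <- run_features(hrv, pup, config, all_edges)
      list(sweep = per_run_correlation(feats$pupil_cum, feats$hrv_feat,
                                       combos_all, config$method),
           report = list(hrv = attr(hrv, "report"),
                         pupil = attr(pup, "report"),
                         n_windows = feats$n_windows))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reports[[i]] <- list(skipped = TRUE, reason = conditionMessage(res))
      message(sprintf("run %d skipped: %s", i, conditionMessage(res)))
    } else {
      k <- length(per_run) + 1L
      per_run[[k]] <- res$sweep[seq_len(nrow(combos)), , drop = FALSE]
      if (!is.null(lit_combos))
        per_run_lit[[k]] <- res$sweep[nrow(combos) + seq_len(nrow(lit_combos)), ,
                                      drop = FALSE]
      reports[[i]] <- res$report
    }
  }
  if (length(per_run) < 2L)
    stop("fewer than 2 runs survived preprocessing")
  group <- aggregate_sweep(per_run, combos, config$cluster)
  top <- rank_top(group, 10)
  named <- if (!is.null(lit_combos)) {
    nm <- aggregate_named(per_run_lit, config$cluster$alpha)
    # on-grid literature combos inherit the sweep's cluster-corrected p
    for (feat in c("lf", "hf", "ratio")) nm[[paste0("p_corr_", feat)]] <- NA_real_
    for (r in seq_len(nrow(nm))) {
      hit <- which(abs(group$lf_lo - nm$lf_lo[r]) < 1e-9 &
                   abs(group$split - nm$split[r]) < 1e-9 &
                   abs(group$hf_hi - nm$hf_hi[r]) < 1e-9)
      if (length(hit) == 1L)
        for (feat in c("lf", "hf", "ratio"))
          nm[[paste0("p_corr_", feat)]][r] <- group[[paste0("p_", feat)]][hit]
    }
    nm
  } else NULL
  out <- list(group = group, top = top, named = named, per_run = per_run,
              reports = reports, combos = combos, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Group metrics for a fixed set of combinations (no lattice correction)
#'
#' Fisher-Z aggregation, uncorrected group p, percent significant runs and
#' geometric mean for a handful of named combinations -- used for the
#' literature bands, which need no multiple-comparison correction of their
#' own.
#'
#' @param run_results list of per-run tables over the same named combos.
#' @param alpha per-run significance level for the percentages.
#' @return data.frame with one row per named combination.
#' @export
aggregate_named <- function(run_results, alpha = 0.05) {
  stopifnot(length(run_results) >= 2L)
  base <- run_results[[1]][, c("lf_lo", "split", "hf_hi")]
  ns <- vapply(run_results, function(d) d$n[1], numeric(1))
  for (feat in c("lf", "hf", "ratio")) {
    rcol <- paste0("r_", feat); pcol <- paste0("p_", feat)
    R <- do.call(rbind, lapply(run_results, function(d) d[[rcol]]))
    P <- do.call(rbind, lapply(run_results, function(d) d[[pcol]]))
    agg <- lapply(seq_len(ncol(R)), function(cix)
      aggregate_runs(R[, cix], ns))
    base[[rcol]] <- vapply(agg, `[[`, numeric(1), "r_group")
    base[[pcol]] <- vapply(agg, `[[`, numeric(1), "p")
    base[[paste0("pct_", feat)]] <- apply(P, 2, pct_significant_runs,
                                          alpha = alpha)
  }
  base$geo_mean <- geometric_mean_score(base$r_lf, base$r_hf, base$r_ratio)
  base
}

# CSV + JSON export of the pipeline result
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$group, file.path(out_dir, "group_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$top, file.path(out_dir, "top10.csv"),
                   row.names = FALSE)
  if (!is.null(result$named))
    utils::write.csv(result$named, file.path(out_dir, "literature_bands.csv"),
                     row.names = FALSE)
  cfg <- result$config
  cfg$ssa <- unclass(cfg$ssa); cfg$cluster <- unclass(cfg$cluster)
  jsonlite::write_json(
    list(config = lapply(unclass(cfg), function(x)
      if (is.list(x)) x else unname(x)),
      n_runs = length(result$per_run),
      reports = result$reports,
      r_version = as.character(getRversion())),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}

#' Condition contrast by Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum comparison of a windowed feature between
#' low- and high-load condition labels, with per-group medians -- the
#' secondary analysis contrasting code sections of low and high cyclomatic
#' complexity.
#'
#' @param values numeric feature values, one per analysis window.
#' @param labels factor/character with exactly two levels; the first level
#'   in sort order is reported as "low".
#' @return list with `median_low`, `median_high`, `p`, `n_low`, `n_high`.
#' @export
condition_contrast <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two condition labels required")
  g <- split(values, labels)
  if (any(lengths(g) == 0L)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(g[[1]], g[[2]],
                                            alternative = "two.sided"))
  list(median_low = stats::median(g[[1]]),
       median_high = stats::median(g[[2]]),
       p = wt$p.value, n_low = length(g[[1]]), n_high = length(g[[2]]))
}

#' Cumulative-power summary across windows
#'
#' Averages the per-window PSDs normalized to unit total power and reports
#' the frequencies at which the cumulative power of the average crosses
#' the given percentiles -- the diagnostic used to justify restricting the
#' sweep to 0-1 Hz.
#'
#' @param wp a [window_psds()] result (or a list of them, pooled).
#' @param percentiles fractions to report (default 0.90, 0.95, 0.975, 0.99).
#' @return list with `freqs`, `mean_density` (unit total power),
#'   `cum_fraction`, and `crossings` (named vector of Hz values).
#' @export
fig_cumulative_power <- function(wp, percentiles = c(0.90, 0.95, 0.975, 0.99)) {
  if (!is.null(wp$density)) wp <- list(wp)
  freqs <- wp[[1]]$freqs
  dens <- do.call(rbind, lapply(wp, function(w) {
    tot <- w$cum[, ncol(w$cum)]
    w$density / tot
  }))
  md <- colMeans(dens)
  cum <- cumtrapz_vec(freqs, md)
  cumf <- cum / cum[length(cum)]
  cross <- vapply(percentiles,
                  function(q) freqs[which(cumf >= q)[1]], numeric(1))
  names(cross) <- sprintf("%g%%", 100 * percentiles)
  list(freqs = freqs, mean_density = md, cum_fraction = cumf,
       crossings = cross)
}
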