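# Synthetic coupled RR / pupil-diameter runs with known planted spectral
# structure. The coupling model: each frequency band (LF, HF) has a slow
# positive "autonomic gain" envelope shared between the two signals within
# a run; band-specific stochastic carriers are multiplied by that envelope,
# so window-to-window band-power fluctuations are correlated between the
# RR and pupil series -- the structure the band sweep is designed to find.

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Narrowband modulator specification
#'
#' Stands in for a band-limited component of the shared sympathetic /
#' parasympathetic drive that modulates both heart rhythm and pupil
#' diameter.
#'
#' @param center_freq centre frequency in Hz (> 0).
#' @param bandwidth full bandwidth in Hz (> 0, with
#'   `center_freq - bandwidth/2 >= 0`).
#' @param gain unitless amplitude multiplier applied where the modulator
#'   enters a signal model.
#' @return list of class `modulator_spec`.
#' @export
modulator_spec <- function(center_freq, bandwidth, gain = 1) {
  if (center_freq <= 0) stop("`center_freq` must be > 0")
  if (bandwidth <= 0) stop("`bandwidth` must be > 0")
  if (center_freq - bandwidth / 2 < 0)
    stop("band must not extend below 0 Hz (center_freq - bandwidth/2 >= 0)")
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 gain = gain), class = "modulator_spec")
}

#' Band-limited stochastic modulator
#'
#' Zero-mean, unit-variance Gaussian noise whose spectral power is confined
#' to `[center - bw/2, center + bw/2]`, realized by shaping white noise in
#' the frequency domain (flat in-band response, zero outside). The flat,
#' sharply edged spectrum is what lets the band sweep resolve planted band
#' limits; see the methods vignette for the comparison with resonator-based
#' constructions.
#'
#' @param spec a [modulator_spec()].
#' @param duration length in seconds.
#' @param fs sampling rate in Hz; must exceed twice the band's upper edge.
#' @param seed integer seed (same seed, same realization).
#' @return A [sampled_signal()] of `floor(duration*fs) + 1` samples.
#' @export
make_band_limited_modulator <- function(spec, duration, fs, seed) {
  stopifnot(inherits(spec, "modulator_spec"))
  f_hi <- spec$center_freq + spec$bandwidth / 2
  if (fs <= 2 * f_hi)
    stop("sampling rate violates the Nyquist precondition fs > 2*(center + bw/2)")
  n <- floor(duration * fs) + 1
  x <- with_seed(seed, band_limited_noise(n, fs, spec$center_freq - spec$bandwidth / 2, f_hi))
  sampled_signal(x, fs, 0)
}

# unit-variance Gaussian noise band-limited to [f_lo, f_hi] via FFT masking
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  W[f < f_lo | f > f_hi] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

# 1/f^beta background noise with standard deviation sd; tapered off above
# `f_top` Hz so the background stays within the sub-2 Hz range where real
# pupil activity lives (fs needed only when tapering)
pink_noise <- function(n, sd, beta = 1, fs = NULL, f_top = 1.0) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(1, seq_len(n - 1))                # guard the DC bin
  k <- pmin(k, n - k + 1)
  W <- W / k^(beta / 2)
  W[1] <- 0
  if (!is.null(fs)) {
    f <- seq(0, n - 1) * fs / n
    f <- pmin(f, fs - f)
    roll <- f_top / 3
    g <- ifelse(f <= f_top, 1,
                ifelse(f <= f_top + roll,
                       0.5 * (1 + cos(pi * (f - f_top) / roll)), 0))
    W <- W * g
  }
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# broadband sub-Hz background: flat to `edge` Hz with a cosine rolloff one
# half-band wide; stands in for slow non-luminance pupil activity
# (accommodation/vergence fluctuations) spread over the analysis range
broadband_noise <- function(n, fs, sd, edge = 1.0) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  roll <- edge / 3
  g <- ifelse(f <= edge, 1,
              ifelse(f <= edge + roll, 0.5 * (1 + cos(pi * (f - edge) / roll)), 0))
  W <- W * g
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

# slow positive gain envelope shared between RR and pupil within one band:
# exp(sigma * u(t)) with u a standardized AR(1) process of time constant
# tau, generated directly at fs (smooth; no interpolation kinks that
# would smear modulator power across the spectrum)
slow_gain_envelope <- function(duration, fs, sigma = 0.4, tau = 100) {
  n <- floor(duration * fs) + 1
  burn <- ceiling(5 * tau * fs)
  phi <- exp(-1 / (fs * tau))
  u <- as.numeric(stats::filter(stats::rnorm(n + burn), phi,
                                method = "recursive"))[-seq_len(burn)]
  u <- (u - mean(u)) / stats::sd(u)
  exp(sigma * u - sigma^2 / 2)
}

#' Synthetic run configuration
#'
#' Defaults emulate the study conditions: ~10-minute task recordings, a
#' 500 Hz eye tracker, RR around 900 ms with canonical-band autonomic
#' modulation, pupil modulators planted in shifted bands (LF
#' `[0.06, 0.29)`, HF `[0.29, 0.49)` Hz by default) on a 1/f background
#' with blink and spike artifacts. Rates and noise levels the source data
#' do not pin down are plausibility choices documented in the methods
#' vignette.
#'
#' @param duration run length in seconds (>= 360, i.e. at least two
#'   180-second analysis windows).
#' @param rr_mean mean RR interval in ms.
#' @param rr_lf,rr_hf [modulator_spec()]s for the RR modulators (canonical
#'   HRV bands); gains are relative RR modulation depths.
#' @param pupil_lf,pupil_hf [modulator_spec()]s for the planted pupil
#'   bands; gains in diameter units (mm).
#' @param pupil_baseline baseline diameter (mm).
#' @param pink_noise_sd standard deviation of the 1/f^beta background (mm).
#' @param pink_exponent spectral exponent beta.
#' @param broadband_sd standard deviation of the band-limited sub-Hz
#'   background component (mm); flat to `broadband_edge` Hz with a cosine
#'   rolloff.
#' @param broadband_edge upper edge of the broadband component (Hz).
#' @param blink_rate blink events per minute.
#' @param blink_duration_mean mean blink duration in ms (log-normal,
#'   sigma 0.3 log-units).
#' @param spike_outlier_rate isolated spike outliers per minute.
#' @param envelope_sigma log-sd of the shared band-gain envelopes.
#' @param envelope_tau correlation time constant of all slow envelopes (s).
#' @param noise_envelope_sigma log-sd of the independent slow envelope
#'   modulating the background noise (makes the noise floor
#'   non-stationary, as in real recordings).
#' @param pupil_fs eye-tracker sampling rate in Hz (>= 16).
#' @param seed integer seed; all derived random streams are functions of it.
#' @return list of class `synthetic_run_config`.
#' @export
synthetic_run_config <- function(duration = 600,
                                 rr_mean = 900,
                                 rr_lf = modulator_spec(0.10, 0.09, 0.05),
                                 rr_hf = modulator_spec(0.275, 0.21, 0.04),
                                 pupil_lf = modulator_spec(0.175, 0.23, 0.26),
                                 pupil_hf = modulator_spec(0.39, 0.20, 0.24),
                                 pupil_baseline = 4.5,
                                 pink_noise_sd = 0.32,
                                 pink_exponent = 1.5,
                                 broadband_sd = 0.40,
                                 broadband_edge = 1.0,
                                 blink_rate = 6,
                                 blink_duration_mean = 200,
                                 spike_outlier_rate = 1,
                                 envelope_sigma = 0.45,
                                 envelope_tau = 40,
                                 noise_envelope_sigma = 0.8,
                                 pupil_fs = 500,
                                 seed = 1L) {
  if (duration < 360) stop("`duration` must be >= 360 s (two analysis windows)")
  if (pupil_fs < 16) stop("`pupil_fs` must be >= 16 Hz")
  if (blink_rate < 0 || spike_outlier_rate < 0)
    stop("artifact rates must be >= 0")
  stopifnot(inherits(rr_lf, "modulator_spec"), inherits(rr_hf, "modulator_spec"),
            inherits(pupil_lf, "modulator_spec"),
            inherits(pupil_hf, "modulator_spec"))
  structure(list(duration = duration, rr_mean = rr_mean, rr_lf = rr_lf,
                 rr_hf = rr_hf, pupil_lf = pupil_lf, pupil_hf = pupil_hf,
                 pupil_baseline = pupil_baseline,
                 pink_noise_sd = pink_noise_sd,
                 pink_exponent = pink_exponent,
                 broadband_sd = broadband_sd,
                 broadband_edge = broadband_edge,
                 noise_envelope_sigma = noise_envelope_sigma,
                 blink_rate = blink_rate,
                 blink_duration_mean = blink_duration_mean,
                 spike_outlier_rate = spike_outlier_rate,
                 envelope_sigma = envelope_sigma,
                 envelope_tau = envelope_tau,
                 pupil_fs = pupil_fs, seed = as.integer(seed)),
            class = "synthetic_run_config")
}

# deterministic sub-seeds for the independent random streams of one run
run_substream <- function(cfg, k)
  as.integer((as.numeric(cfg$seed) * 97 + k * 1009) %% 2147483629)

# shared band envelopes at a given rate (same realization for RR and pupil)
run_envelope <- function(cfg, band, fs) {
  k <- if (band == "lf") 1L else 2L
  with_seed(run_substream(cfg, k),
            slow_gain_envelope(cfg$duration, fs, cfg$envelope_sigma,
                               cfg$envelope_tau))
}

# envelope-modulated unit-variance band carrier
run_modulator <- function(cfg, spec, band, fs, stream) {
  env <- run_envelope(cfg, band, fs)
  n <- floor(cfg$duration * fs) + 1
  car <- with_seed(run_substream(cfg, stream),
                   band_limited_noise(n, fs, spec$center_freq - spec$bandwidth / 2,
                                      spec$center_freq + spec$bandwidth / 2))
  s <- env * car
  (s - mean(s)) / stats::sd(s)
}

#' Synthesize an RR-interval series
#'
#' Instantaneous `RR(t) = rr_mean * (1 + g_lf * s_lf(t) + g_hf * s_hf(t))`
#' with unit-variance band modulators sharing the run's autonomic gain
#' envelopes; beats are generated by accumulating `RR(t)` from time zero.
#' Configurations whose gains drive RR outside physiological bounds
#' (300-2000 ms) are rejected.
#'
#' @param cfg a [synthetic_run_config()].
#' @return An [rr_series()] spanning `[0, duration]`.
#' @export
synthesize_rr <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_run_config"))
  fs <- 8
  s_lf <- run_modulator(cfg, cfg$rr_lf, "lf", fs, 3L)
  s_hf <- run_modulator(cfg, cfg$rr_hf, "hf", fs, 4L)
  rr_t <- cfg$rr_mean * (1 + cfg$rr_lf$gain * s_lf + cfg$rr_hf$gain * s_hf)
  if (any(rr_t < 300 | rr_t > 2000))
    stop("gain combination drives RR outside physiological bounds [300, 2000] ms")
  tt <- (seq_along(rr_t) - 1) / fs
  beats <- numeric(ceiling(cfg$duration / (min(rr_t) / 1000)) + 2)
  nb <- 1L
  beats[1] <- 0
  t_cur <- 0
  while (TRUE) {
    rr_now <- stats::approx(tt, rr_t, xout = t_cur, rule = 2)$y
    t_next <- t_cur + rr_now / 1000
    if (t_next > cfg$duration) break
    nb <- nb + 1L
    beats[nb] <- t_next
    t_cur <- t_next
  }
  rr_series(beats[seq_len(nb)])
}

#' Synthesize a pupil-diameter stream
#'
#' Baseline plus the planted-band modulators (sharing the run's autonomic
#' envelopes with the RR series), a 1/f^beta background, blink stretches
#' flagged invalid (Poisson onsets, log-normal durations) and isolated
#' spike outliers left valid for the outlier filter to find.
#'
#' @param cfg a [synthetic_run_config()].
#' @return A [sampled_signal()] at `cfg$pupil_fs` with validity mask.
#'   Attribute `"artifacts"` records blink and spike positions.
#' @export
synthesize_pupil <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_run_config"))
  fs <- cfg$pupil_fs
  n <- floor(cfg$duration * fs) + 1
  fs_mod <- 8
  tt_mod <- (seq_len(floor(cfg$duration * fs_mod) + 1) - 1) / fs_mod
  tt <- (seq_len(n) - 1) / fs
  up <- function(x) stats::approx(tt_mod, x, xout = tt, rule = 2)$y
  s_lf <- up(run_modulator(cfg, cfg$pupil_lf, "lf", fs_mod, 5L))
  s_hf <- up(run_modulator(cfg, cfg$pupil_hf, "hf", fs_mod, 6L))
  noise <- numeric(n)
  if (cfg$pink_noise_sd > 0)
    noise <- noise + with_seed(run_substream(cfg, 7L),
                               pink_noise(n, cfg$pink_noise_sd,
                                          cfg$pink_exponent, fs))
  if (cfg$broadband_sd > 0)
    noise <- noise + with_seed(run_substream(cfg, 11L),
                               broadband_noise(n, fs, cfg$broadband_sd,
                                               cfg$broadband_edge))
  if (cfg$noise_envelope_sigma > 0 && any(noise != 0)) {
    # non-stationary noise floor: one independent slow gain envelope
    # modulates the whole background, as slow waxing and waning of
    # non-autonomic pupil activity does in real recordings
    n_env <- with_seed(run_substream(cfg, 10L),
                       slow_gain_envelope(cfg$duration, fs,
                                          cfg$noise_envelope_sigma,
                                          cfg$envelope_tau))
    noise <- noise * n_env
  }
  x <- cfg$pupil_baseline + cfg$pupil_lf$gain * s_lf +
    cfg$pupil_hf$gain * s_hf + noise
  valid <- rep(TRUE, n)
  blinks <- NULL
  if (cfg$blink_rate > 0) {
    blinks <- with_seed(run_substream(cfg, 8L), {
      n_ev <- stats::rpois(1, cfg$blink_rate / 60 * cfg$duration)
      if (n_ev > 0) {
        onset <- sort(stats::runif(n_ev, 0, cfg$duration))
        dur <- stats::rlnorm(n_ev,
                             log(cfg$blink_duration_mean / 1000) - 0.3^2 / 2,
                             0.3)
        data.frame(onset = onset, duration = dur)
      } else NULL
    })
    if (!is.null(blinks)) {
      for (b in seq_len(nrow(blinks))) {
        # samples whose time falls inside [onset, onset + duration]
        i0 <- max(1L, ceiling(blinks$onset[b] * fs) + 1L)
        i1 <- min(n, floor((blinks$onset[b] + blinks$duration[b]) * fs) + 1L)
        if (i1 >= i0) {
          valid[i0:i1] <- FALSE
          x[i0:i1] <- 0                  # device reports garbage during blinks
        }
      }
    }
  }
  spikes <- NULL
  if (cfg$spike_outlier_rate > 0) {
    spikes <- with_seed(run_substream(cfg, 9L), {
      n_sp <- stats::rpois(1, cfg$spike_outlier_rate / 60 * cfg$duration)
      if (n_sp > 0) {
        idx <- sample(which(valid), min(n_sp, sum(valid)))
        amp <- sample(c(-1, 1), length(idx), replace = TRUE) *
          stats::runif(length(idx), 0.5, 1.2)
        data.frame(index = idx, amplitude = amp)
      } else NULL
    })
    if (!is.null(spikes)) x[spikes$index] <- x[spikes$index] + spikes$amplitude
  }
  out <- sampled_signal(x, fs, 0, valid)
  attr(out, "artifacts") <- list(blinks = blinks, spikes = spikes)
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Independent seeded runs for `n_subjects x runs_per_subject`, all sharing
#' the configuration template (per-run seeds are derived from the master
#' seed), together with the planted band limits for oracle checks.
#'
#' @param n_subjects,runs_per_subject cohort dimensions (>= 1).
#' @param cfg a [synthetic_run_config()] template; its `seed` is ignored.
#' @param seed master seed.
#' @return list with `runs` (each: `subject`, `run`, `cfg`, `rr`
#'   ([rr_series()]), `pupil` ([sampled_signal()])) and `ground_truth`
#'   (`planted_lf_band`, `planted_hf_band`).
#' @export
generate_dataset <- function(n_subjects, runs_per_subject,
                             cfg = synthetic_run_config(), seed = 1L) {
  if (n_subjects < 1 || runs_per_subject < 1) stop("counts must be >= 1")
  n_runs <- n_subjects * runs_per_subject
  run_seeds <- with_seed(seed, sample.int(2147483629L, n_runs))
  runs <- vector("list", n_runs)
  idx <- 1L
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(runs_per_subject)) {
      rcfg <- cfg
      rcfg$seed <- run_seeds[idx]
      runs[[idx]] <- list(subject = s, run = r, cfg = rcfg,
                          rr = synthesize_rr(rcfg),
                          pupil = synthesize_pupil(rcfg))
      idx <- idx + 1L
    }
  }
  gt <- list(
    planted_lf_band = c(cfg$pupil_lf$center_freq - cfg$pupil_lf$bandwidth / 2,
                        cfg$pupil_lf$center_freq + cfg$pupil_lf$bandwidth / 2),
    planted_hf_band = c(cfg$pupil_hf$center_freq - cfg$pupil_hf$bandwidth / 2,
                        cfg$pupil_hf$center_freq + cfg$pupil_hf$bandwidth / 2))
  list(runs = runs, ground_truth = gt)
}

#' Write a synthetic run to CSV files
#'
#' Pupil samples as `(time_s, diameter, valid)`, beats as `(beat_time_s)`,
#' plus a JSON sidecar with the configuration and planted bands.
#'
#' @param run one element of `generate_dataset()$runs`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_csv <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("s%02d_r%02d", run$subject, run$run)
  pupil_path <- file.path(dir, paste0(stem, "_pupil.csv"))
  beat_path <- file.path(dir, paste0(stem, "_beats.csv"))
  json_path <- file.path(dir, paste0(stem, "_config.json"))
  utils::write.csv(data.frame(time_s = signal_times(run$pupil),
                              diameter = run$pupil$values,
                              valid = as.integer(run$pupil$valid)),
                   pupil_path, row.names = FALSE)
  utils::write.csv(data.frame(beat_time_s = run$rr$beat_times),
                   beat_path, row.names = FALSE)
  cfg <- run$cfg
  cfg_flat <- lapply(cfg, function(el)
    if (inherits(el, "modulator_spec")) unclass(el) else el)
  jsonlite::write_json(list(subject = run$subject, run = run$run,
                            config = cfg_flat),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(pupil = pupil_path, beats = beat_path, config = json_path))
}

#' Read a pupil CSV written by [write_run_csv()]
#'
#' @param path CSV with columns `time_s`, `diameter`, `valid`.
#' @return A [sampled_signal()].
#' @export
read_pupil_csv <- function(path) {
  d <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(d$time_s))
  sampled_signal(d$diameter, round(fs, 6), d$time_s[1], d$valid == 1)
}

#' Read a beat-annotation CSV written by [write_run_csv()]
#'
#' @param path CSV with column `beat_time_s`.
#' @return An [rr_series()].
#' @export
read_beats_csv <- function(path) rr_series(utils::read.csv(path)$beat_time_s)
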