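# shared test helpers: small, fast synthetic configurations

# artifact-free run at a modest tracker rate, for unit tests that do not
# exercise blink handling
quick_cfg <- function(seed = 1L, ...) {
  synthetic_run_config(duration = 400, pupil_fs = 50, blink_rate = 0,
                       spike_outlier_rate = 0, seed = seed, ...)
}

# sampled sinusoid helper
sine_signal <- function(freq, fs, duration, amp = 1, t0 = 0) {
  tt <- t0 + seq(0, duration, by = 1 / fs)
  sampled_signal(amp * sin(2 * pi * freq * tt), fs, t0)
}

# amplitude measured away from filter edges
central_amp <- function(x, drop_frac = 0.1) {
  n <- length(x)
  i <- seq(floor(n * drop_frac) + 1, ceiling(n * (1 - drop_frac)))
  max(abs(x[i]))
}
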