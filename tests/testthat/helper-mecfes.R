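# Shared fixtures, built in code.

constant_envelope <- function(n_bins, level) {
  env <- make_envelope("rest", duration = n_bins * 0.06 + 0.03)
  env <- env[seq_len(n_bins), ]
  env$vmc_uV <- rep(level, n_bins)
  class(env) <- c("mecfes_envelope", class(tibble::tibble()))
  env
}

# templates only, everything stochastic off (quasi-stationary model)
template_only_model <- function(adc_range = 5000) {
  artifact_model(jitter_sd = 0, reflex_prob = 0, reflex_amp_sd = 0,
                 hum_amp = 0, motion_rate = 0, motion_amp = 0,
                 adc_range = adc_range)
}

signal_from <- function(samples) {
  tibble::tibble(
    time_s = (seq_along(samples) - 1L) / 2000,
    amplitude_uV = as.numeric(samples)
  ) -> x
  class(x) <- c("mecfes_signal", class(tibble::tibble()))
  x
}

# steady-state mean of the trailing fraction of a series
steady <- function(x, frac = 0.4) mean(tail(x, max(1L, floor(length(x) * frac))))

# amplitude of a steady-state sinusoidal response (fit at known frequency)
tone_amplitude <- function(y, freq, fs = 2000, skip = 1000) {
  y <- y[-seq_len(skip)]
  t <- (seq_along(y) - 1) / fs
  co <- stats::coef(stats::lm(y ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t)))
  sqrt(co[2]^2 + co[3]^2)
}
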