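#' Build a voluntary-contraction (VMC) envelope scenario
#'
#' The envelope is the latent quantity the whole device tries to estimate: the
#' RMS amplitude (in microvolts) of the voluntary wrist-extensor EMG, sampled
#' once per 60 ms inter-stimulus bin (16.667 Hz).
#'
#' @param profile One of `"rest"` (identically zero), `"step"` (zero for the
#'   first half of the duration, `level` for the second), `"ramp"` (linear rise
#'   from 0 to `level`) or `"sinusoid"` (`level/2 * (1 + sin(2*pi*freq*t))`,
#'   so values span `[0, level]` with mean `level/2`).
#' @param duration Scenario duration in seconds. The envelope has
#'   `floor(duration / 0.06)` bins.
#' @param level Peak voluntary EMG amplitude, microvolt RMS.
#' @param seed Optional integer seed; the built-in profiles are deterministic,
#'   the argument exists so scenario definitions always carry one.
#' @param freq Sinusoid frequency in Hz (default 1/3 Hz, i.e. a 3 s period, an
#'   integer number of bins so the discrete mean is exactly `level/2`).
#' @return A tibble of class `mecfes_envelope` with columns `bin`, `time_s`,
#'   `vmc_uV`.
#' @examples
#' make_envelope("step", duration = 6, level = 10)
#' @export
make_envelope <- function(profile = c("rest", "step", "ramp", "sinusoid"),
                          duration, level = 10, seed = NULL, freq = 1 / 3) {
  if (length(profile) != 1L || !profile %in% c("rest", "step", "ramp", "sinusoid")) {
    stop("unknown envelope profile: ", paste(profile, collapse = ", "), call. = FALSE)
  }
  stopifnot(duration > 0, level >= 0)
  n <- floor(duration / BIN_DT + 1e-9)
  if (n < 1L) stop("duration shorter than one 60 ms bin", call. = FALSE)
  t <- (seq_len(n) - 1L) * BIN_DT
  v <- switch(profile,
    rest = numeric(n),
    step = ifelse(seq_len(n) > n / 2, level, 0),
    ramp = level * t / max(t[n], BIN_DT),
    sinusoid = level / 2 * (1 + sin(2 * pi * freq * t))
  )
  new_envelope(tibble::tibble(bin = seq_len(n), time_s = t, vmc_uV = v))
}

#' @noRd
rest_envelope <- function(n_bins) {
  new_envelope(tibble::tibble(
    bin = seq_len(n_bins),
    time_s = (seq_len(n_bins) - 1L) * BIN_DT,
    vmc_uV = numeric(n_bins)
  ))
}

#' @noRd
new_envelope <- function(x) {
  stopifnot(all(c("bin", "time_s", "vmc_uV") %in% names(x)))
  if (any(x$vmc_uV < 0)) stop("envelope values must be non-negative", call. = FALSE)
  class(x) <- c("mecfes_envelope", class(tibble::tibble()))
  x
}

#' Stimulation pulse schedule
#'
#' One biphasic pulse per 60 ms bin; only the per-bin current amplitude varies.
#'
#' @param amplitudes Per-bin stimulation amplitude, mA (recycled if length 1
#'   together with `n_bins`).
#' @param n_bins Number of bins when `amplitudes` is a scalar.
#' @param pulse_offset Sample index of the pulse within its bin (default 0:
#'   the bin starts at the pulse).
#' @return A tibble of class `mecfes_schedule` with columns `bin`,
#'   `amplitude_mA`; the pulse offset is carried as an attribute.
#' @export
stim_schedule <- function(amplitudes, n_bins = length(amplitudes), pulse_offset = 0L) {
  amplitudes <- rep_len(amplitudes, n_bins)
  if (any(amplitudes < 0)) stop("stimulation amplitudes must be non-negative", call. = FALSE)
  stopifnot(pulse_offset >= 0, pulse_offset < BIN_LEN)
  out <- tibble::tibble(bin = seq_len(n_bins), amplitude_mA = as.numeric(amplitudes))
  attr(out, "pulse_offset") <- as.integer(pulse_offset)
  class(out) <- c("mecfes_schedule", class(tibble::tibble()))
  out
}

#' Stimulated-recording contamination model
#'
#' Describes everything the recording contains besides the voluntary EMG:
#' per-pulse quasi-stationary responses (direct stimulation artifact plus
#' M-wave, both scaling linearly with stimulation current), randomly occurring
#' late reflex events (H-reflex / F-wave) near 40 ms post pulse, 50 Hz mains
#' hum, Poisson-timed motion-artifact transients, and the 16-bit ADC.
#' Response amplitudes in real recordings depend on electrode placement and
#' are not standardised; the defaults are plausible surface-recording values
#' and every one of them is a parameter.
#'
#' @param artifact_template Direct-artifact waveform, microvolt per mA, one
#'   value per sample of the 120-sample bin. The default is a biphasic
#'   double-exponential confined to samples 0-19 (so the first blanking window
#'   removes it entirely when timing is ideal).
#' @param mwave_template Compound muscle action potential waveform, microvolt
#'   per mA; default a damped sinusoid over samples 5-45.
#' @param jitter_sd Pulse-to-pulse multiplicative variability of the combined
#'   response (fraction, SD of a zero-mean Gaussian factor).
#' @param reflex_prob Per-pulse probability of a late reflex event.
#' @param reflex_template Unit-peak reflex waveform centred at sample 80
#'   (40 ms post pulse), +/- 8 samples of support.
#' @param reflex_amp_sd Scale (microvolt) of the half-normal reflex amplitude.
#' @param reflex_latency_jitter Maximum latency shift in samples (+/-).
#' @param hum_amp 50 Hz mains interference amplitude, microvolt.
#' @param motion_rate Motion-artifact event rate, events per second.
#' @param motion_amp Motion-artifact amplitude scale, microvolt.
#' @param adc_bits ADC resolution (16).
#' @param adc_range ADC full scale referred to input, +/- microvolt (the 60 dB
#'   amplifier gain is folded into input-referred units).
#' @return A list of class `mecfes_artifact_model`.
#' @seealso [silent_artifact_model()] for the all-off model.
#' @export
artifact_model <- function(artifact_template = default_artifact_template(),
                           mwave_template = default_mwave_template(),
                           jitter_sd = 0.02,
                           reflex_prob = 0.05,
                           reflex_template = default_reflex_template(),
                           reflex_amp_sd = 20,
                           reflex_latency_jitter = 3L,
                           hum_amp = 1,
                           motion_rate = 0.2,
                           motion_amp = 50,
                           adc_bits = 16L,
                           adc_range = 5000) {
  stopifnot(
    length(artifact_template) <= BIN_LEN, length(mwave_template) <= BIN_LEN,
    length(reflex_template) <= BIN_LEN,
    jitter_sd >= 0, reflex_prob >= 0, reflex_prob <= 1,
    reflex_amp_sd >= 0, hum_amp >= 0, motion_rate >= 0, motion_amp >= 0,
    adc_bits == 16L, adc_range > 0
  )
  pad <- function(x) c(x, numeric(BIN_LEN - length(x)))
  structure(list(
    artifact_template = pad(artifact_template),
    mwave_template = pad(mwave_template),
    jitter_sd = jitter_sd,
    reflex_prob = reflex_prob,
    reflex_template = pad(reflex_template),
    reflex_amp_sd = reflex_amp_sd,
    reflex_latency_jitter = as.integer(reflex_latency_jitter),
    hum_amp = hum_amp,
    motion_rate = motion_rate,
    motion_amp = motion_amp,
    adc_bits = as.integer(adc_bits),
    adc_range = adc_range
  ), class = "mecfes_artifact_model")
}

#' @rdname artifact_model
#' @details `silent_artifact_model()` returns a model with every contamination
#'   source off (zero templates, no jitter, no reflexes, no hum, no motion);
#'   injecting it into a trace is the identity map, which several invariants
#'   rely on.
#' @export
silent_artifact_model <- function(adc_range = 5000) {
  artifact_model(
    artifact_template = numeric(0), mwave_template = numeric(0),
    jitter_sd = 0, reflex_prob = 0, reflex_template = numeric(0),
    reflex_amp_sd = 0, hum_amp = 0, motion_rate = 0, motion_amp = 0,
    adc_range = adc_range
  )
}

#' @noRd
default_artifact_template <- function(peak_uV_per_mA = 150) {
  t <- 0:19
  w <- exp(-t / 3) - 0.6 * exp(-t / 9)   # fast positive lobe, slower negative tail
  peak_uV_per_mA * w / max(abs(w))
}

#' @noRd
default_mwave_template <- function(peak_uV_per_mA = 40) {
  w <- numeric(46)
  t <- 5:45
  w[t + 1L] <- sin(2 * pi * (t - 5) / 20) * exp(-(t - 5) / 12)
  peak_uV_per_mA * w / max(abs(w))
}

#' @noRd
default_reflex_template <- function(centre = 80L, half_width = 8L) {
  w <- numeric(BIN_LEN)
  t <- (centre - half_width):(centre + half_width)
  w[t + 1L] <- 0.5 * (1 + cos(pi * (t - centre) / half_width))
  w
}

#' Synthesize clean voluntary surface EMG from an envelope
#'
#' The voluntary EMG is modelled as Gaussian white noise band-limited to
#' 20-450 Hz (a standard surface-EMG band) and scaled so that the sample
#' standard deviation within each 120-sample bin equals the envelope value for
#' that bin. Scaling uses the band filter's analytic white-noise RMS gain, so
#' generation is strictly causal and the per-bin SD matches the envelope in
#' expectation (Monte-Carlo, not exactly, for any finite trace).
#'
#' @param envelope A [make_envelope()] tibble.
#' @param seed Integer seed; the same seed reproduces the trace bit-exactly.
#' @return A tibble of class `mecfes_signal` with columns `time_s`,
#'   `amplitude_uV` (2000 Hz sampling, `nrow = 120 * n_bins`).
#' @export
synthesize_emg <- function(envelope, seed = 1L) {
  n_bins <- nrow(envelope)
  filt <- design_bandpass(EMG_BAND[1], EMG_BAND[2], order = 2L)
  g <- impulse_rms_gain(filt)
  x <- with_seed(seed, stats::rnorm(n_bins * BIN_LEN))
  y <- iir_filter(filt$b, filt$a, x)$y
  scale <- rep(envelope$vmc_uV / g, each = BIN_LEN)
  new_signal(y * scale)
}

#' @noRd
new_signal <- function(samples) {
  n <- length(samples)
  if (n %% BIN_LEN != 0L) {
    stop("signal length (", n, ") is not a multiple of the ", BIN_LEN,
         "-sample bin", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1L) / FS,
    amplitude_uV = as.numeric(samples)
  )
  class(out) <- c("mecfes_signal", class(tibble::tibble()))
  out
}

#' @noRd
signal_bins <- function(trace) {
  x <- if (is.data.frame(trace)) trace$amplitude_uV else as.numeric(trace)
  if (length(x) %% BIN_LEN != 0L) {
    stop("sample count (", length(x), ") is not a multiple of ", BIN_LEN, call. = FALSE)
  }
  matrix(x, nrow = BIN_LEN)
}

# Pre-draw every random component of the contamination so the batch injector
# and the streaming closed-loop simulator consume identical randomness.
#' @noRd
contamination_draws <- function(model, n_bins, seed) {
  with_seed(seed, {
    jitter <- stats::rnorm(n_bins, 0, model$jitter_sd)
    reflex_on <- stats::runif(n_bins) < model$reflex_prob
    reflex_amp <- abs(stats::rnorm(n_bins, 0, 1)) * model$reflex_amp_sd
    jmax <- model$reflex_latency_jitter
    reflex_shift <- if (jmax > 0) sample(seq(-jmax, jmax), n_bins, replace = TRUE)
                    else integer(n_bins)
    hum_phase <- stats::runif(1, 0, 2 * pi)
    duration <- n_bins * BIN_DT
    n_motion <- stats::rpois(1, model$motion_rate * duration)
    motion <- list(
      t0 = stats::runif(n_motion, 0, duration),
      width = stats::runif(n_motion, 0.010, 0.050),
      amp = model$motion_amp * stats::runif(n_motion, 0.5, 1.5) *
        sample(c(-1, 1), n_motion, replace = TRUE)
    )
    list(jitter = jitter, reflex_on = reflex_on, reflex_amp = reflex_amp,
         reflex_shift = reflex_shift, hum_phase = hum_phase, motion = motion)
  })
}

# Amplitude-independent background (hum + motion transients) for the whole trace.
#' @noRd
background_trace <- function(model, n_bins, draws) {
  n <- n_bins * BIN_LEN
  t <- (seq_len(n) - 1L) / FS
  bg <- if (model$hum_amp > 0) {
    model$hum_amp * sin(2 * pi * 50 * t + draws$hum_phase)
  } else numeric(n)
  m <- draws$motion
  for (i in seq_along(m$t0)) {
    idx <- which(abs(t - m$t0[i]) < m$width[i] / 2)
    if (length(idx)) {
      bg[idx] <- bg[idx] + m$amp[i] * 0.5 * (1 + cos(2 * pi * (t[idx] - m$t0[i]) / m$width[i]))
    }
  }
  bg
}

# Per-pulse contamination added to bin k when stimulating at `amp` mA.
#' @noRd
pulse_response_bin <- function(model, k, amp, draws, pulse_offset = 0L) {
  out <- numeric(BIN_LEN)
  if (amp > 0) {
    resp <- (model$artifact_template + model$mwave_template) * amp * (1 + draws$jitter[k])
    if (pulse_offset > 0L) {
      resp <- c(numeric(pulse_offset), resp)[seq_len(BIN_LEN)]
    }
    out <- out + resp
    if (draws$reflex_on[k]) {
      refl <- shift_template(model$reflex_template, draws$reflex_shift[k])
      out <- out + refl * draws$reflex_amp[k]
    }
  }
  out
}

#' @noRd
shift_template <- function(w, shift) {
  if (shift == 0L) return(w)
  n <- length(w)
  out <- numeric(n)
  if (shift > 0) out[(1 + shift):n] <- w[1:(n - shift)]
  else out[1:(n + shift)] <- w[(1 - shift):n]
  out
}

#' Inject stimulation responses and background noise into a trace
#'
#' Adds, per bin, the current-scaled quasi-stationary response (direct
#' artifact + M-wave) with multiplicative pulse-to-pulse jitter, a late reflex
#' event with probability `reflex_prob`, continuous 50 Hz hum, and
#' Poisson-timed motion transients. Purely additive: with a zero-amplitude
#' schedule and every contamination source off, the output equals the input.
#'
#' @param emg A `mecfes_signal` trace (e.g. from [synthesize_emg()]).
#' @param schedule A [stim_schedule()] with one amplitude per bin of `emg`.
#' @param model An [artifact_model()].
#' @param seed Integer seed for the stochastic contamination components.
#' @return A `mecfes_signal` tibble, same length as the input.
#' @export
inject_responses <- function(emg, schedule, model, seed = 1L) {
  bins <- signal_bins(emg)
  n_bins <- ncol(bins)
  if (n_bins != nrow(schedule)) {
    stop("trace has ", n_bins, " bins but schedule has ", nrow(schedule),
         call. = FALSE)
  }
  offset <- attr(schedule, "pulse_offset") %||% 0L
  draws <- contamination_draws(model, n_bins, seed)
  for (k in seq_len(n_bins)) {
    bins[, k] <- bins[, k] +
      pulse_response_bin(model, k, schedule$amplitude_mA[k], draws, offset)
  }
  new_signal(as.numeric(bins) + background_trace(model, n_bins, draws))
}

#' Quantize a trace through the 16-bit ADC
#'
#' Rounds every sample to the `2^16`-level grid spanning `+/- adc_range`
#' microvolts and clips (saturates) samples beyond full scale, as a real
#' converter does.
#'
#' @param trace A `mecfes_signal` tibble.
#' @param model An [artifact_model()] supplying `adc_bits` and `adc_range`.
#' @return A quantized `mecfes_signal` tibble.
#' @export
adc_quantize <- function(trace, model = artifact_model()) {
  new_signal(quantize_vec(trace$amplitude_uV, model))
}

# An infinite range disables the converter (used by the stability analysis,
# where the quantizer's microvolt deadband is not the object of study).
#' @noRd
quantize_vec <- function(x, model) {
  if (is.infinite(model$adc_range)) return(x)
  step <- 2 * model$adc_range / 2^model$adc_bits
  step * round(pmin(pmax(x, -model$adc_range), model$adc_range) / step)
}

#' @importFrom rlang %||%
NULL
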