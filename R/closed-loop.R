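#' Run the full closed-loop MeCFES simulation
#'
#' Couples the signal generator, the VMC estimator and the piecewise-linear
#' controller bin by bin. The command computed from bin `k` drives the
#' stimulation pulse of bin `k + 1` (one 60 ms actuation delay), so bin `k`'s
#' recording contains the voluntary EMG for bin `k` plus the responses to the
#' previous command. Stimulation responses that survive the estimator
#' (leakage) feed back positively into the VMC estimate; with too high a gain
#' the loop latches to full output.
#'
#' With [silent_artifact_model()] the loop reduces bit-exactly to open-loop
#' estimation of the quantized clean EMG.
#'
#' @param envelope True VMC envelope, a [make_envelope()] tibble.
#' @param model An [artifact_model()].
#' @param device A [device_config()].
#' @param estimator An [estimator_config()].
#' @param seed Integer seed (EMG and contamination use derived substreams).
#' @param mode `"active"` or `"paused"` (paused commands are always 0 mA).
#' @return A tibble of class `mecfes_loop` with per-bin columns `bin`,
#'   `time_s`, `envelope_uV`, `arv_uV`, `vmc_uV`, `command_mA`; attributes
#'   `latched` (see [detect_full_on()]), `device`, `estimator`.
#' @export
run_closed_loop <- function(envelope, model = artifact_model(),
                            device = device_config(),
                            estimator = estimator_config(tau = device$tau),
                            seed = 1L, mode = c("active", "paused")) {
  mode <- match.arg(mode)
  n <- nrow(envelope)
  stopifnot(n >= 1L)
  emg_bins <- signal_bins(synthesize_emg(envelope, seed))
  draws <- contamination_draws(model, n, (seed + 1L) %% .Machine$integer.max)
  bg <- background_trace(model, n, draws)
  filt <- design_bandpass(estimator$band_low, estimator$band_high)
  alpha <- 1 - exp(-BIN_DT / estimator$tau)

  fstate <- NULL
  prev_fb <- numeric(BIN_LEN)
  v <- 0
  cmd_prev <- 0
  a_raw <- vmc <- cmd <- numeric(n)
  for (k in seq_len(n)) {
    idx <- ((k - 1L) * BIN_LEN + 1L):(k * BIN_LEN)
    raw <- emg_bins[, k] + pulse_response_bin(model, k, cmd_prev, draws) + bg[idx]
    raw <- quantize_vec(raw, model)
    fr <- iir_filter(filt$b, filt$a, raw, fstate)
    fstate <- fr$state
    cbin <- if (estimator$comb) {
      if (k == 1L) numeric(BIN_LEN) else fr$y - prev_fb
    } else fr$y
    prev_fb <- fr$y
    a_raw[k] <- mean(abs(cbin[estimator$retained]))
    v <- alpha * a_raw[k] + (1 - alpha) * v
    vmc[k] <- v
    cmd[k] <- if (mode == "active") pwl_map(v, device) else 0
    cmd_prev <- cmd[k]
  }

  out <- tibble::tibble(
    bin = seq_len(n), time_s = (seq_len(n) - 1L) * BIN_DT,
    envelope_uV = envelope$vmc_uV, arv_uV = a_raw, vmc_uV = vmc,
    command_mA = cmd
  )
  attr(out, "latched") <- detect_full_on(cmd, envelope, device)
  attr(out, "device") <- device
  attr(out, "estimator") <- estimator
  class(out) <- c("mecfes_loop", class(tibble::tibble()))
  out
}

#' Measure stimulation-response leakage through the estimator
#'
#' Runs the estimator on a zero-EMG trace stimulated at a constant probe
#' current and reports the steady-state VMC estimate per mA: the residue of
#' the stimulation responses that blanking and the comb filter fail to
#' suppress. For a model with no pulse-to-pulse jitter, no reflexes, no hum
#' and no motion the quasi-stationary responses are bin-periodic and the comb
#' cancels them completely (leakage 0 up to the decayed filter transient).
#'
#' @param model An [artifact_model()].
#' @param estimator An [estimator_config()].
#' @param probe_mA Constant probe stimulation amplitude, mA (> 0).
#' @param n_bins Number of bins simulated (steady state is the mean estimate
#'   over the last third).
#' @param seed Integer seed.
#' @return Leakage in microvolt of estimate per mA of stimulation.
#' @export
measure_leakage <- function(model, estimator = estimator_config(),
                            probe_mA = 10, n_bins = 300L, seed = 1L) {
  stopifnot(probe_mA > 0, n_bins >= 30L)
  env <- rest_envelope(n_bins)
  emg <- synthesize_emg(env, seed)
  rec <- inject_responses(emg, stim_schedule(probe_mA, n_bins), model, seed)
  est <- estimate_vmc(adc_quantize(rec, model), estimator)
  steady <- mean(est$vmc_uV[(floor(2 * n_bins / 3) + 1L):n_bins])
  steady / probe_mA
}

# Deterministic leakage base: quasi-stationary templates only, nothing else.
#' @noRd
leakage_base_model <- function(adc_range = Inf) {
  artifact_model(jitter_sd = 0, reflex_prob = 0, reflex_amp_sd = 0,
                 hum_amp = 0, motion_rate = 0, motion_amp = 0,
                 adc_range = adc_range)
}

#' Construct a model with a prescribed leakage
#'
#' For stability analysis a known, constant leakage is needed. This scales
#' the quasi-stationary response templates so that, with the comb filter
#' disabled, the measured steady-state leakage equals `lambda` (the scaling
#' is calibrated via [measure_leakage()]; leakage is linear in template
#' amplitude). A small 50 Hz hum is included as the perturbation that lets an
#' unstable rest fixed point escape; quantization is disabled
#' (`adc_range = Inf`) so the analysis probes the loop dynamics, not the
#' converter's microvolt-scale deadband.
#'
#' @param lambda Target leakage, microvolt per mA (>= 0).
#' @param estimator The [estimator_config()] the loop will use (its comb flag
#'   must be off, as leakage of this deterministic kind only survives a
#'   comb-less estimator).
#' @param hum_amp Perturbation hum amplitude, microvolt.
#' @return A calibrated `mecfes_artifact_model`.
#' @export
leakage_model <- function(lambda, estimator, hum_amp = 0.3) {
  stopifnot(lambda >= 0)
  if (estimator$comb) {
    stop("leakage_model() requires an estimator with the comb filter disabled",
         call. = FALSE)
  }
  base <- leakage_base_model()
  m <- base
  if (lambda > 0) {
    cal_est <- estimator_config(
      band_low = estimator$band_low, band_high = estimator$band_high,
      blank1 = estimator$blank1, blank2 = estimator$blank2,
      comb = FALSE, tau = 0.2
    )
    lam0 <- measure_leakage(base, cal_est, probe_mA = 10, n_bins = 120L, seed = 1L)
    s <- lambda / lam0
    m$artifact_template <- base$artifact_template * s
    m$mwave_template <- base$mwave_template * s
  } else {
    m$artifact_template <- numeric(BIN_LEN)
    m$mwave_template <- numeric(BIN_LEN)
  }
  m$hum_amp <- hum_amp
  m
}

#' Map latch-up over a gain x leakage grid
#'
#' Runs [run_closed_loop()] at rest for every combination of controller gain
#' and calibrated leakage and records whether the loop latched to full output.
#' At zero offset the small-signal criterion predicts latch-up iff
#' `gain * leakage >= 1` (the rest fixed point of `v <- leakage *
#' min(max_stim, gain * v)` loses stability).
#'
#' @param gains Controller gains, mA per microvolt.
#' @param leakages Leakages, microvolt per mA.
#' @param device Base [device_config()] (its `gain` is replaced grid-wise).
#' @param estimator An [estimator_config()]; the comb flag is forced off (see
#'   [leakage_model()]).
#' @param seed Integer seed.
#' @param duration Rest-scenario duration per grid point, seconds.
#' @param hum_amp Perturbation hum amplitude, microvolt.
#' @return A tibble of class `mecfes_stability` with columns `gain`,
#'   `leakage`, `loop_gain` (their product) and `latched`.
#' @export
stability_map <- function(gains, leakages, device = device_config(tau = 0.5),
                          estimator = estimator_config(comb = FALSE, tau = device$tau),
                          seed = 1L, duration = 30, hum_amp = 0.3) {
  stopifnot(length(gains) >= 1L, length(leakages) >= 1L)
  estimator$comb <- FALSE
  env <- make_envelope("rest", duration = duration)
  grid <- tidyr::expand_grid(leakage = leakages, gain = gains)
  grid$latched <- purrr::pmap_lgl(grid, function(leakage, gain) {
    model <- leakage_model(leakage, estimator, hum_amp = hum_amp)
    dev <- device_config(offset = device$offset, gain = gain,
                         max_stim = device$max_stim, tau = device$tau)
    tr <- run_closed_loop(env, model, dev, estimator, seed = seed)
    attr(tr, "latched")
  })
  out <- tibble::tibble(gain = grid$gain, leakage = grid$leakage,
                        loop_gain = grid$gain * grid$leakage,
                        latched = grid$latched)
  class(out) <- c("mecfes_stability", class(tibble::tibble()))
  out
}

#' Scalar fixed-point oracle for latch-up
#'
#' Iterates the small-signal loop map directly -- `v <- (1 - alpha) * v +
#' alpha * (leakage * command + drive)` with `command = pwl_map(v)` delayed by
#' one bin -- without any signal synthesis or filtering. Used as an
#' independent prediction of the latch-up boundary: at zero offset the
#' iteration diverges to saturation iff `gain * leakage > 1`.
#'
#' @param gain Controller gain, mA per microvolt.
#' @param leakage Leakage, microvolt per mA.
#' @param device A [device_config()] (offset, max_stim, tau).
#' @param drive Constant excitation in microvolt of ARV (the hum residue in
#'   the simulator's terms).
#' @param n_bins Number of iterations.
#' @param window Trailing bins that must be pinned at `max_stim`.
#' @return Logical: does the iteration latch?
#' @export
latch_oracle <- function(gain, leakage, device, drive = 0.1,
                         n_bins = 500L, window = 33L) {
  alpha <- 1 - exp(-BIN_DT / device$tau)
  v <- 0
  cmd_prev <- 0
  dev <- device_config(offset = device$offset, gain = gain,
                       max_stim = device$max_stim, tau = device$tau)
  cmd <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    v <- (1 - alpha) * v + alpha * (leakage * cmd_prev + drive)
    cmd[k] <- pwl_map(v, dev)
    cmd_prev <- cmd[k]
  }
  all(cmd[(n_bins - window + 1L):n_bins] >= dev$max_stim)
}

#' Tracking error of a closed-loop run against its target envelope
#'
#' Root-mean-square difference between the commanded stimulation and the
#' command an ideal, noise-free estimator would have produced for the target
#' envelope (the envelope scaled by [arv_expectation_factor()], smoothed by
#' the same IIR, mapped through the same piecewise-linear law). The first
#' `5 * tau` seconds are skipped to exclude the smoothing transient.
#'
#' @param trace A `mecfes_loop` tibble from [run_closed_loop()].
#' @param target The target [make_envelope()] tibble (same bin count).
#' @return RMS command error, mA.
#' @export
tracking_error <- function(trace, target) {
  if (nrow(trace) != nrow(target)) {
    stop("loop trace (", nrow(trace), " bins) and target (", nrow(target),
         " bins) differ in length", call. = FALSE)
  }
  estimator <- attr(trace, "estimator")
  device <- attr(trace, "device")
  ideal_v <- smooth_arv(target$vmc_uV * arv_expectation_factor(estimator), estimator)
  ideal_cmd <- pwl_map(ideal_v, device)
  skip <- ceiling(5 * estimator$tau / BIN_DT)
  if (skip >= nrow(trace)) stop("trace shorter than the 5*tau transient", call. = FALSE)
  keep <- (skip + 1L):nrow(trace)
  sqrt(mean((trace$command_mA[keep] - ideal_cmd[keep])^2))
}
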