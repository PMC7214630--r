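#' Estimator configuration
#'
#' Parameters of the VMC estimation chain: second-order bandpass corners,
#' the two per-bin blanking windows, the inter-pulse comb filter switch and
#' the smoothing time constant.
#'
#' @param band_low,band_high -3 dB corners of the second-order bandpass, Hz.
#' @param blank1 First blanking window as a half-open sample range `[from, to)`
#'   within the 120-sample bin; default `c(0, 20)` removes the direct
#'   stimulation response.
#' @param blank2 Second blanking window, default `c(70, 90)`: a symmetric
#'   20-sample window around sample 80 where H-reflexes and F-waves typically
#'   fall (the device preset; the exact placement is configurable).
#' @param comb If `TRUE` (default) apply the first-order comb filter that
#'   subtracts the previous bin, notching every multiple of the 16.667 Hz
#'   stimulation rate including DC and thereby cancelling quasi-stationary
#'   per-pulse responses.
#' @param tau Time constant of the first-order IIR output smoother, seconds
#'   (default 1 s).
#' @return A list of class `mecfes_estimator_config`.
#' @export
estimator_config <- function(band_low = 16, band_high = 500,
                             blank1 = c(0, 20), blank2 = c(70, 90),
                             comb = TRUE, tau = 1) {
  stopifnot(
    band_low > 0, band_high > band_low, band_high <= FS / 2,
    length(blank1) == 2L, length(blank2) == 2L,
    blank1[1] >= 0, blank1[2] <= BIN_LEN, blank1[1] <= blank1[2],
    blank2[1] >= 0, blank2[2] <= BIN_LEN, blank2[1] <= blank2[2],
    tau > 0
  )
  w1 <- seq2(blank1[1], blank1[2])
  w2 <- seq2(blank2[1], blank2[2])
  if (length(intersect(w1, w2)) > 0) {
    stop("blanking windows must be disjoint", call. = FALSE)
  }
  retained <- setdiff(0:(BIN_LEN - 1L), c(w1, w2)) + 1L  # 1-based indices
  if (length(retained) == 0L) stop("blanking retains no samples", call. = FALSE)
  structure(list(
    band_low = band_low, band_high = band_high,
    bin_len = BIN_LEN, blank1 = blank1, blank2 = blank2,
    comb = isTRUE(comb), tau = tau, retained = retained
  ), class = "mecfes_estimator_config")
}

#' @noRd
seq2 <- function(from, to) if (to > from) seq.int(from, to - 1L) else integer(0)

#' Samples retained after blanking
#'
#' @param config An [estimator_config()].
#' @return Integer vector of 1-based sample indices within a bin that survive
#'   both blanking windows (80 samples with the defaults).
#' @export
retained_samples <- function(config = estimator_config()) config$retained

#' Second-order bandpass filter
#'
#' Applies the estimator's 2-pole Butterworth bandpass (default -3 dB corners
#' 16 and 500 Hz) from zero initial state, emulating the device's analog
#' front-end filter.
#'
#' @param trace A `mecfes_signal` tibble.
#' @param config An [estimator_config()].
#' @return Filtered `mecfes_signal` tibble.
#' @export
bandpass <- function(trace, config = estimator_config()) {
  stopifnot(nrow(trace) > 0)
  filt <- design_bandpass(config$band_low, config$band_high)
  new_signal(iir_filter(filt$b, filt$a, trace$amplitude_uV)$y)
}

#' Segment a trace into 120-sample inter-stimulus bins
#'
#' @param trace A `mecfes_signal` tibble or numeric vector whose length is a
#'   multiple of 120.
#' @return A `120 x n_bins` numeric matrix; column `k` is bin `k` and
#'   `as.numeric()` of the matrix reproduces the trace.
#' @export
segment_bins <- function(trace) signal_bins(trace)

#' First-order inter-pulse comb filter
#'
#' Subtracts the previous bin sample-by-sample: `out[, k] = bins[, k] -
#' bins[, k - 1]`, with the first output bin defined as zero (it has no
#' predecessor). Any exactly bin-periodic input -- the quasi-stationary
#' stimulation responses -- is annihilated from the second bin on.
#'
#' @param bins A `120 x n` bin matrix from [segment_bins()].
#' @param enabled If `FALSE`, return the input unchanged.
#' @return A bin matrix of the same shape.
#' @export
comb_filter <- function(bins, enabled = TRUE) {
  stopifnot(is.matrix(bins), ncol(bins) >= 1L)
  if (!enabled) return(bins)
  out <- bins
  out[, 1L] <- 0
  if (ncol(bins) > 1L) {
    out[, -1L] <- bins[, -1L, drop = FALSE] - bins[, -ncol(bins), drop = FALSE]
  }
  out
}

#' Apply the blanking windows to one bin
#'
#' @param bin Numeric vector of length 120.
#' @param config An [estimator_config()].
#' @return The retained samples (length 80 with the default windows).
#' @export
apply_blanking <- function(bin, config = estimator_config()) {
  stopifnot(length(bin) == config$bin_len)
  bin[config$retained]
}

#' Average rectified value over the retained samples of a bin
#'
#' @param bin Numeric vector of length 120.
#' @param retained 1-based indices of the samples entering the mean (blanked
#'   samples are excluded from the divisor, not zero-filled).
#' @return Mean absolute amplitude, microvolt.
#' @export
arv <- function(bin, retained = retained_samples()) {
  if (length(retained) == 0L) stop("retained sample set is empty", call. = FALSE)
  mean(abs(bin[retained]))
}

#' First-order IIR smoothing of the per-bin ARV series
#'
#' `v[k] = alpha * a[k] + (1 - alpha) * v[k-1]` with
#' `alpha = 1 - exp(-0.06 / tau)` (exact discretisation of a first-order lag
#' at the 60 ms bin rate) and `v[0] = 0`. Unity DC gain; a unit step reaches
#' `1 - exp(-1)` (63.2 %) after `tau` seconds.
#'
#' @param arv_series Numeric vector, one ARV per bin (microvolt).
#' @param config An [estimator_config()] supplying `tau`.
#' @return Numeric vector of smoothed values, same length.
#' @export
smooth_arv <- function(arv_series, config = estimator_config()) {
  stopifnot(config$tau > 0)
  alpha <- 1 - exp(-BIN_DT / config$tau)
  v <- numeric(length(arv_series))
  prev <- 0
  for (k in seq_along(arv_series)) {
    prev <- alpha * arv_series[k] + (1 - alpha) * prev
    v[k] <- prev
  }
  v
}

#' Estimate the voluntary muscle contraction from a recorded trace
#'
#' Runs the full estimation chain: bandpass -> bin segmentation -> comb filter
#' -> blanking -> average rectified value -> IIR smoothing. The result is the
#' per-bin VMC estimate the controller maps to a stimulation command.
#'
#' The estimate is the uncorrected ARV of the comb output, as the device
#' computes it: for stochastic EMG the comb (difference of nearly independent
#' bins) inflates the expected ARV by `sqrt(2)`, and the bandpass attenuates
#' the EMG band slightly; [arv_expectation_factor()] gives the combined
#' expected estimate per microvolt of true envelope.
#'
#' @param trace A `mecfes_signal` tibble (raw recording).
#' @param config An [estimator_config()].
#' @return A tibble of class `mecfes_vmc` with columns `bin`, `time_s`,
#'   `arv_uV` (pre-smoothing) and `vmc_uV`; the configuration is attached as
#'   attribute `"config"`.
#' @export
estimate_vmc <- function(trace, config = estimator_config()) {
  filtered <- bandpass(trace, config)
  bins <- segment_bins(filtered)
  cb <- comb_filter(bins, config$comb)
  a_raw <- apply(abs(cb[config$retained, , drop = FALSE]), 2L, mean)
  v <- smooth_arv(a_raw, config)
  out <- tibble::tibble(
    bin = seq_along(a_raw),
    time_s = (seq_along(a_raw) - 1L) * BIN_DT,
    arv_uV = as.numeric(a_raw),
    vmc_uV = v
  )
  attr(out, "config") <- config
  class(out) <- c("mecfes_vmc", class(tibble::tibble()))
  out
}

#' Expected estimator output per microvolt of true envelope
#'
#' For clean Gaussian EMG of constant envelope `A` the steady-state estimate
#' is `A * arv_expectation_factor(config)`: the half-normal mean factor
#' `sqrt(2/pi)`, times `sqrt(2)` when the comb filter differences two nearly
#' independent bins, times the RMS gain of the estimator bandpass over the
#' synthetic 20-450 Hz EMG band (computed from the designed filters' impulse
#' responses).
#'
#' @param config An [estimator_config()].
#' @return A positive scalar.
#' @export
arv_expectation_factor <- function(config = estimator_config()) {
  synth <- design_bandpass(EMG_BAND[1], EMG_BAND[2], order = 2L)
  est <- design_bandpass(config$band_low, config$band_high)
  h_synth <- iir_filter(synth$b, synth$a, c(1, numeric(4095)))$y
  h_both <- iir_filter(est$b, est$a, h_synth)$y
  g_band <- sqrt(sum(h_both^2) / sum(h_synth^2))
  sqrt(2 / pi) * (if (config$comb) sqrt(2) else 1) * g_band
}
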