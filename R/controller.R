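#' Device (controller) configuration
#'
#' The three key user parameters of the stimulation controller: the offset
#' (the VMC level from which stimulation starts), the proportional gain, and
#' the maximum stimulation amplitude; plus the shared smoothing time constant.
#'
#' @param offset Threshold VMC, microvolt (>= 0).
#' @param gain Proportional gain, mA per microvolt (>= 0).
#' @param max_stim Maximum stimulation amplitude, mA (> 0).
#' @param tau Smoothing time constant shared with the estimator, s.
#' @return A list of class `mecfes_device_config`.
#' @export
device_config <- function(offset = 0, gain = 1, max_stim = 30, tau = 1) {
  if (!(is.numeric(offset) && offset >= 0)) stop("offset must be >= 0", call. = FALSE)
  if (!(is.numeric(gain) && gain >= 0)) stop("gain must be >= 0", call. = FALSE)
  if (!(is.numeric(max_stim) && max_stim > 0)) stop("max_stim must be > 0", call. = FALSE)
  if (!(is.numeric(tau) && tau > 0)) stop("tau must be > 0", call. = FALSE)
  structure(list(offset = offset, gain = gain, max_stim = max_stim, tau = tau),
            class = "mecfes_device_config")
}

#' Piecewise-linear VMC-to-stimulation map
#'
#' The three-segment threshold / linear / saturation law:
#' `min(max_stim, gain * max(0, vmc - offset))`. Continuous, nondecreasing
#' and Lipschitz in `vmc` with constant `gain`; output always within
#' `[0, max_stim]`.
#'
#' @param vmc VMC estimate(s), microvolt (vectorised, must be >= 0).
#' @param config A [device_config()].
#' @return Stimulation amplitude(s), mA.
#' @examples
#' pwl_map(10, device_config(offset = 5, gain = 2, max_stim = 30))  # 10 mA
#' @export
pwl_map <- function(vmc, config) {
  if (!inherits(config, "mecfes_device_config")) {
    stop("config must be a device_config()", call. = FALSE)
  }
  if (any(vmc < 0)) stop("vmc must be non-negative", call. = FALSE)
  pmin(config$max_stim, config$gain * pmax(0, vmc - config$offset))
}

# Adjustment ranges and step sizes for the push-button interface. Device
# steps are not standardised; these are exposed as the package's defaults.
BUTTON_STEPS <- list(
  offset = list(step = 0.5, min = 0, max = 100),          # additive, uV
  gain = list(step = 1.1, min = 0.01, max = 100),         # multiplicative
  max_stim = list(step = 1, min = 1, max = 60)            # additive, mA
)
ADJUST_CYCLE <- c("none", "offset", "gain", "max_stim")

#' Device state for the three-button interface
#'
#' @param config A [device_config()].
#' @param mode `"active"` (stimulation under myoelectric control) or
#'   `"paused"` (no stimulation output).
#' @param adjust Currently selected parameter for +/- adjustment.
#' @return A list of class `mecfes_device_state` with a transition `log`
#'   (each entry surrogates a buzzer beep on the device).
#' @export
device_state <- function(config = device_config(), mode = c("active", "paused"),
                         adjust = ADJUST_CYCLE) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  structure(list(mode = mode, adjust = adjust, config = config, log = character()),
            class = "mecfes_device_state")
}

#' Advance the button state machine
#'
#' A short press of the mode button toggles paused/active; a long press cycles
#' the parameter-adjustment mode `none -> offset -> gain -> max_stim -> none`;
#' plus/minus nudge the selected parameter by its step (offset 0.5 uV,
#' gain x1.1, max_stim 1 mA), clamped to its valid range. Plus/minus with no
#' parameter selected is a logged no-op with a warning.
#'
#' @param state A [device_state()].
#' @param events Character vector of events, each one of `"short_mode"`,
#'   `"long_mode"`, `"plus"`, `"minus"`; applied in order.
#' @return The updated `mecfes_device_state`.
#' @export
step_buttons <- function(state, events) {
  stopifnot(inherits(state, "mecfes_device_state"))
  for (event in events) state <- step_one_button(state, event)
  state
}

#' @noRd
step_one_button <- function(state, event) {
  note <- function(s, msg) { s$log <- c(s$log, msg); s }
  switch(event,
    short_mode = {
      state$mode <- if (state$mode == "active") "paused" else "active"
      note(state, paste("mode ->", state$mode))
    },
    long_mode = {
      i <- match(state$adjust, ADJUST_CYCLE)
      state$adjust <- ADJUST_CYCLE[(i %% length(ADJUST_CYCLE)) + 1L]
      note(state, paste("adjust ->", state$adjust))
    },
    plus = adjust_param(state, +1L),
    minus = adjust_param(state, -1L),
    stop("unknown button event: ", event, call. = FALSE)
  )
}

#' @noRd
adjust_param <- function(state, direction) {
  if (state$adjust == "none") {
    warning("no parameter selected for adjustment; press ignored", call. = FALSE)
    state$log <- c(state$log, "adjust ignored (none selected)")
    return(state)
  }
  p <- state$adjust
  spec <- BUTTON_STEPS[[p]]
  old <- state$config[[p]]
  new <- if (p == "gain") {
    if (direction > 0) old * spec$step else old / spec$step
  } else {
    old + direction * spec$step
  }
  new <- min(max(new, spec$min), spec$max)
  state$config[[p]] <- new
  state$log <- c(state$log, sprintf("%s: %.4g -> %.4g", p, old, new))
  state
}

#' Detect a latched full-on state
#'
#' The hallmark of closed-loop instability: stimulation pinned at the maximum
#' while the user is actually at rest. Returns `TRUE` iff the command equals
#' `max_stim` over the last `window` bins while the true envelope is zero over
#' those bins.
#'
#' @param stim_series Commanded stimulation per bin, mA.
#' @param envelope True VMC envelope per bin, microvolt (a [make_envelope()]
#'   tibble or numeric vector); `NULL` means the scenario is rest throughout.
#' @param config A [device_config()] supplying `max_stim`.
#' @param window Number of trailing bins that must be pinned (default 33,
#'   about 2 s).
#' @return Logical flag.
#' @export
detect_full_on <- function(stim_series, envelope = NULL, config = device_config(),
                           window = 33L) {
  stopifnot(window >= 1L)
  n <- length(stim_series)
  if (n < window) return(FALSE)
  env <- if (is.null(envelope)) numeric(n)
         else if (is.data.frame(envelope)) envelope$vmc_uV
         else as.numeric(envelope)
  stopifnot(length(env) == n)
  tail_idx <- (n - window + 1L):n
  all(stim_series[tail_idx] >= config$max_stim) && all(env[tail_idx] == 0)
}
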