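#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recorded or synthetic signal trace
#'
#' @param object A `mecfes_signal` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mecfes_signal
#' @export
autoplot.mecfes_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$amplitude_uV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot a VMC estimate (raw ARV and smoothed estimate)
#'
#' @param object A `mecfes_vmc` tibble from [estimate_vmc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mecfes_vmc
#' @export
autoplot.mecfes_vmc <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("arv_uV", "vmc_uV"),
                              names_to = "series", values_to = "uV")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$uV,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(arv_uV = "grey60", vmc_uV = "black"),
      labels = c(arv_uV = "raw ARV", vmc_uV = "smoothed VMC")) +
    ggplot2::labs(x = "time (s)", y = "estimate (µV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a closed-loop trace
#'
#' True envelope and VMC estimate (microvolt) on one panel, commanded
#' stimulation (mA) on a second.
#'
#' @param object A `mecfes_loop` tibble from [run_closed_loop()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mecfes_loop
#' @export
autoplot.mecfes_loop <- function(object, ...) {
  x <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(time_s = x$time_s, value = x$envelope_uV,
                   series = "true envelope (µV)", panel = "estimate"),
    tibble::tibble(time_s = x$time_s, value = x$vmc_uV,
                   series = "VMC estimate (µV)", panel = "estimate"),
    tibble::tibble(time_s = x$time_s, value = x$command_mA,
                   series = "command (mA)", panel = "command")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a latch-up stability map
#'
#' Gain x leakage grid coloured by the latched flag, with the analytic
#' small-signal boundary `gain = 1 / leakage` overlaid.
#'
#' @param object A `mecfes_stability` tibble from [stability_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mecfes_stability
#' @export
autoplot.mecfes_stability <- function(object, ...) {
  x <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$gain),
                                       y = factor(.data$leakage),
                                       fill = .data$latched)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#4477aa", `TRUE` = "#cc3311")) +
    ggplot2::labs(x = "gain (mA/µV)", y = "leakage (µV/mA)",
                  fill = "latched") +
    ggplot2::theme_minimal()
  p
}

#' @importFrom rlang .data
NULL
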