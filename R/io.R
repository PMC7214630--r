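# Plain-text table readers/writers. All files are comma-separated with a
# mandatory header; numeric output carries 6 significant digits.

#' Path to a packaged example / fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
mecfes_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "mecfes"))
  } else {
    path <- system.file("extdata", file, package = "mecfes", mustWork = FALSE)
    if (!nzchar(path)) stop("no packaged file named ", file, call. = FALSE)
    path
  }
}

#' @noRd
write_table6 <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  readr::write_csv(x, path)
  invisible(path)
}

#' @noRd
read_table_checked <- function(path, required, what, col_types = NULL) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  # readr's own parsing-issue warning is redundant: problems() is turned
  # into an error just below
  x <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                                        progress = FALSE, col_types = col_types))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    stop("failed to parse ", what, " file ", path, " at line ",
         pr$row[1], ": expected ", pr$expected[1], ", got ", pr$actual[1],
         call. = FALSE)
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read / write signal traces, schedules and VMC tables
#'
#' Signal files are `(time_s, amplitude_uV)` with one row per 2 kHz sample;
#' schedule files are `(bin, amplitude_mA)`; VMC tables are
#' `(bin, time_s, arv_uV, vmc_uV)`.
#'
#' @param path File path.
#' @param trace,schedule,estimate The corresponding tibbles.
#' @return The read tibble (readers) or the path, invisibly (writers).
#' @name signal_io
NULL

#' @rdname signal_io
#' @export
read_signal <- function(path) {
  x <- read_table_checked(path, c("time_s", "amplitude_uV"), "signal",
                          col_types = readr::cols(
                            time_s = readr::col_double(),
                            amplitude_uV = readr::col_double()))
  if (nrow(x) == 0L) stop("signal file ", path, " contains no samples", call. = FALSE)
  new_signal_checked(x$amplitude_uV)
}

# like new_signal() but with a file-oriented error message
#' @noRd
new_signal_checked <- function(samples) {
  if (length(samples) %% BIN_LEN != 0L) {
    stop("signal length (", length(samples), " samples) is not a multiple of the ",
         BIN_LEN, "-sample stimulation bin", call. = FALSE)
  }
  new_signal(samples)
}

#' @rdname signal_io
#' @export
write_signal <- function(trace, path) write_table6(trace, path)

#' @rdname signal_io
#' @export
read_schedule <- function(path) {
  x <- read_table_checked(path, c("bin", "amplitude_mA"), "schedule",
                          col_types = readr::cols(
                            bin = readr::col_double(),
                            amplitude_mA = readr::col_double()))
  stim_schedule(x$amplitude_mA)
}

#' @rdname signal_io
#' @export
write_schedule <- function(schedule, path) write_table6(schedule, path)

#' @rdname signal_io
#' @export
write_vmc <- function(estimate, path) write_table6(estimate, path)

#' @rdname signal_io
#' @export
read_vmc <- function(path) {
  read_table_checked(path, c("bin", "time_s", "arv_uV", "vmc_uV"), "VMC")
}

#' Read IPPA / QUEST record files
#'
#' IPPA files carry one row per participant with columns `id`, `pre`, `fu`,
#' optionally `change`, `q9`, `level`; QUEST files either respondent-level
#' item scores or an `(item, mean, sd)` table.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_ippa <- function(path) {
  x <- read_table_checked(path, c("pre", "fu"), "IPPA")
  if (nrow(x) == 0L) stop("IPPA file ", path, " contains no records", call. = FALSE)
  bad <- which(x$pre < 1 | x$pre > 25 | x$fu < 1 | x$fu > 25)
  if (length(bad)) {
    stop("IPPA scores outside [1, 25] in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname read_ippa
#' @export
read_quest <- function(path) {
  x <- read_table_checked(path, character(0), "QUEST")
  if (nrow(x) == 0L) stop("QUEST file ", path, " contains no records", call. = FALSE)
  x
}

#' Read a run-configuration document
#'
#' A YAML document with optional blocks `scenario` (profile, duration_s,
#' level_uV, freq_hz), `schedule` (amplitude_mA), `model` (any
#' [artifact_model()] argument), `estimator` (any [estimator_config()]
#' argument, with `blank1`/`blank2` as two-element ranges), `device`
#' (offset_uV, gain_mA_per_uV, max_stim_mA, tau_s), `stability` (gains,
#' leakages, duration_s), `outcomes` (ippa, quest, ippa_summary file paths)
#' and a top-level `seed`.
#'
#' @param path YAML file path, or a list already in this shape.
#' @return A named list of class `mecfes_run_config` with filled-in defaults.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping", call. = FALSE)
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "mecfes_run_config")
}

#' @noRd
config_envelope <- function(cfg) {
  sc <- cfg$scenario %||% list()
  make_envelope(
    profile = sc$profile %||% "rest",
    duration = sc$duration_s %||% 6,
    level = sc$level_uV %||% 10,
    seed = cfg$seed,
    freq = sc$freq_hz %||% (1 / 3)
  )
}

#' @noRd
config_model <- function(cfg) {
  m <- cfg$model %||% list()
  if (identical(m, "silent")) return(silent_artifact_model())
  do.call(artifact_model, m)
}

#' @noRd
config_estimator <- function(cfg) {
  e <- cfg$estimator %||% list()
  e$blank1 <- unlist(e$blank1 %||% c(0, 20))
  e$blank2 <- unlist(e$blank2 %||% c(70, 90))
  do.call(estimator_config, e)
}

#' @noRd
config_device <- function(cfg) {
  d <- cfg$device %||% list()
  device_config(
    offset = d$offset_uV %||% 0,
    gain = d$gain_mA_per_uV %||% 1,
    max_stim = d$max_stim_mA %||% 30,
    tau = d$tau_s %||% 1
  )
}
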