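#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an IPPA cohort summary
#'
#' One row per participant with the change score and the per-person
#' large-effect flag (change divided by the reference SD exceeding the
#' threshold).
#'
#' @param x A `mecfes_ippa_cohort` from [cohort_summary()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mecfes_ippa_cohort
#' @export
tidy.mecfes_ippa_cohort <- function(x, ...) {
  r <- x$records
  out <- tibble::tibble(
    id = if ("id" %in% names(r)) r$id else as.character(seq_len(nrow(r))),
    pre = r$pre, fu = r$fu,
    change = r$pre - r$fu,
    effect_large = (r$pre - r$fu) / x$sd_used > x$effect_threshold
  )
  if ("q9" %in% names(r)) out$q9 <- parse_q9(r)
  if ("level" %in% names(r)) out$level <- r$level
  out
}

#' Glance at an IPPA cohort summary
#'
#' @inheritParams tidy.mecfes_ippa_cohort
#' @return A one-row tibble of the cohort statistics.
#' @method glance mecfes_ippa_cohort
#' @export
glance.mecfes_ippa_cohort <- function(x, ...) {
  tibble::tibble(
    n = x$n, mean_pre = x$mean_pre, mean_fu = x$mean_fu,
    mean_change = x$mean_change, sd_change = x$sd_change,
    effect_size = x$effect_size, n_effect_large = x$n_effect_large,
    n_positive = x$n_positive, p_value = x$p_value,
    q9_positive = x$q9_total
  )
}

#' Tidy / glance a QUEST summary
#'
#' @param x A `mecfes_quest` from [quest_summary()].
#' @param ... Unused.
#' @return `tidy()`: the per-item tibble; `glance()`: a one-row tibble with
#'   the total score.
#' @method tidy mecfes_quest
#' @export
tidy.mecfes_quest <- function(x, ...) x$items

#' @rdname tidy.mecfes_quest
#' @method glance mecfes_quest
#' @export
glance.mecfes_quest <- function(x, ...) {
  tibble::tibble(total = x$total, n_items = nrow(x$items),
                 single_respondent = isTRUE(x$single_respondent))
}
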