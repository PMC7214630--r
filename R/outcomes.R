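#' IPPA score of a set of problem items
#'
#' The Individually Prioritized Problem Assessment asks the respondent to name
#' up to seven problem activities and rate each for importance (1 = not
#' important ... 5 = very important) and difficulty (1 = easy ... 5 =
#' impossible). The score for a phase is the mean over items of importance
#' times difficulty, ranging 1 to 25. At follow-up the baseline importance
#' ratings are reused with the new difficulty ratings.
#'
#' @param items A data frame with integer columns `importance`,
#'   `difficulty_baseline` and (for the follow-up score)
#'   `difficulty_followup`, all in 1-5, at most 7 rows.
#' @param phase `"baseline"` or `"followup"`.
#' @return The score, a scalar in `[1, 25]`.
#' @examples
#' items <- tibble::tibble(importance = 4, difficulty_baseline = 3,
#'                         difficulty_followup = 1)
#' ippa_score(items, "baseline")  # 12
#' @export
ippa_score <- function(items, phase = c("baseline", "followup")) {
  phase <- match.arg(phase)
  if (!is.data.frame(items) || nrow(items) == 0L) {
    stop("items must be a non-empty data frame", call. = FALSE)
  }
  if (nrow(items) > 7L) stop("at most 7 problem items are allowed", call. = FALSE)
  diff_col <- paste0("difficulty_", phase)
  needed <- c("importance", diff_col)
  if (!all(needed %in% names(items))) {
    stop("items must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  imp <- items$importance
  dif <- items[[diff_col]]
  check_rating(imp, "importance")
  check_rating(dif, diff_col)
  mean(imp * dif)
}

#' @noRd
check_rating <- function(x, what) {
  if (any(is.na(x)) || any(x < 1 | x > 5) || any(x != round(x))) {
    stop(what, " ratings must be integers in 1..5", call. = FALSE)
  }
}

#' IPPA change score
#'
#' Baseline minus follow-up score. Because importance is held fixed, the
#' change ranges from -20 (all items very important and easy, made impossible
#' by the device) to +20 (very important, impossible items made easy).
#'
#' @param baseline,followup Scores in `[1, 25]` from [ippa_score()].
#' @return The change score, in `[-20, 20]`.
#' @export
ippa_change <- function(baseline, followup) {
  if (any(baseline < 1 | baseline > 25) || any(followup < 1 | followup > 25)) {
    stop("IPPA scores must lie in [1, 25]", call. = FALSE)
  }
  baseline - followup
}

#' Cohort statistics for IPPA pre/follow-up scores
#'
#' Computes the cohort summary: mean pre, follow-up and change scores, the
#' SD of the change, the paired effect size `mean(change) / sd(change)`
#' (Cohen's d for paired data; "large" if it exceeds 0.8), the number of
#' participants whose individual change exceeds `0.8 * sd`, the number with a
#' strictly positive change, a paired Wilcoxon signed-rank test on
#' (pre, follow-up) (zero differences dropped, normal approximation with
#' continuity and tie correction), and -- when the records carry a
#' `Q9-Usefulness` response and a neurological level -- the count of positive
#' responses overall and by C5/C6/C7 level group.
#'
#' @param records A data frame with numeric columns `pre` and `fu` (one row
#'   per participant) and optionally `q9` (`"Yes"`/`"No"` or logical) and
#'   `level` (e.g. `"C6A"`; grouped by its first two characters).
#' @param sd_ref Optional reference SD of the change used for the per-person
#'   effect threshold (e.g. a previously published summary SD); default the
#'   sample SD of the observed changes.
#' @param effect_threshold Per-person large-effect threshold (default 0.8).
#' @return An object of class `mecfes_ippa_cohort`; see [glance.mecfes_ippa_cohort()]
#'   and [tidy.mecfes_ippa_cohort()].
#' @export
cohort_summary <- function(records, sd_ref = NULL, effect_threshold = 0.8) {
  if (!is.data.frame(records) || nrow(records) < 2L) {
    stop("need at least 2 participant records", call. = FALSE)
  }
  if (!all(c("pre", "fu") %in% names(records))) {
    stop("records must have columns pre and fu", call. = FALSE)
  }
  pre <- records$pre
  fu <- records$fu
  change <- ippa_change(pre, fu)
  sd_change <- stats::sd(change)
  sd_used <- sd_ref %||% sd_change
  wil <- stats::wilcox.test(pre, fu, paired = TRUE, exact = FALSE, correct = TRUE)

  q9 <- parse_q9(records)
  q9_by_group <- NULL
  q9_total <- NA_integer_
  if (!is.null(q9)) {
    q9_total <- sum(q9)
    if ("level" %in% names(records)) {
      q9_by_group <- tibble::tibble(group = toupper(substr(records$level, 1, 2)), q9 = q9) |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(n = dplyr::n(), q9_positive = sum(.data$q9), .groups = "drop")
    }
  }

  structure(list(
    n = length(change),
    mean_pre = mean(pre), mean_fu = mean(fu),
    mean_change = mean(change), sd_change = sd_change,
    effect_size = effect_size(mean(change), sd_change),
    sd_used = sd_used,
    effect_threshold = effect_threshold,
    n_effect_large = sum(change / sd_used > effect_threshold),
    n_positive = sum(change > 0),
    wilcoxon = wil, p_value = wil$p.value,
    q9_total = q9_total, q9_by_group = q9_by_group,
    records = tibble::as_tibble(records)
  ), class = "mecfes_ippa_cohort")
}

#' Paired effect size from summary statistics
#'
#' `mean / sd` of the change score (Cohen's d for paired data); considered
#' large above 0.8.
#'
#' @param mean_change,sd_change Summary statistics of the change score.
#' @return The effect size.
#' @export
effect_size <- function(mean_change, sd_change) {
  stopifnot(sd_change > 0)
  mean_change / sd_change
}

#' @noRd
parse_q9 <- function(records) {
  if (!"q9" %in% names(records)) return(NULL)
  q <- records$q9
  if (is.logical(q)) return(q)
  ql <- tolower(trimws(as.character(q)))
  if (!all(ql %in% c("yes", "no"))) {
    stop("q9 must be Yes/No (or logical)", call. = FALSE)
  }
  ql == "yes"
}

#' @export
print.mecfes_ippa_cohort <- function(x, ...) {
  cat(sprintf("IPPA cohort summary (n = %d)\n", x$n))
  cat(sprintf("  mean pre %.2f, follow-up %.2f, change %.2f (SD %.2f)\n",
              x$mean_pre, x$mean_fu, x$mean_change, x$sd_change))
  cat(sprintf("  effect size %.2f; %d/%d above %.1f x SD; %d with positive change\n",
              x$effect_size, x$n_effect_large, x$n, x$effect_threshold, x$n_positive))
  cat(sprintf("  paired Wilcoxon signed-rank p = %.2g\n", x$p_value))
  if (!is.na(x$q9_total)) cat(sprintf("  Q9 usefulness positive: %d/%d\n", x$q9_total, x$n))
  if (!is.null(x$q9_by_group)) {
    for (i in seq_len(nrow(x$q9_by_group))) {
      g <- x$q9_by_group[i, ]
      cat(sprintf("    %s: %d of %d positive\n", g$group, g$q9_positive, g$n))
    }
  }
  invisible(x)
}

#' Summarise QUEST satisfaction ratings
#'
#' The QUEST device subscale has eight items (dimensions, weight,
#' adjustments, safety, durability, ease of use, comfort, effectiveness),
#' each rated 1 (not satisfied at all) to 5 (very satisfied). The total score
#' is the mean of the item scores.
#'
#' Accepts either respondent-level data (one row per respondent, one column
#' per item, ratings 1-5) or an already-aggregated item table with columns
#' `item`, `mean` (and optionally `sd`), in which case the total is the mean
#' of the item means.
#'
#' @param x A data frame in one of the two layouts above.
#' @return An object of class `mecfes_quest` with an `items` tibble
#'   (`item`, `mean`, `sd`, `n`) and a `total` score.
#' @export
quest_summary <- function(x) {
  if (!is.data.frame(x) || nrow(x) == 0L) {
    stop("x must be a non-empty data frame", call. = FALSE)
  }
  if (all(c("item", "mean") %in% names(x))) {
    items <- tibble::tibble(
      item = as.character(x$item),
      mean = as.numeric(x$mean),
      sd = if ("sd" %in% names(x)) as.numeric(x$sd) else NA_real_,
      n = NA_integer_
    )
    if (any(items$mean < 1 | items$mean > 5)) {
      stop("item means must lie in [1, 5]", call. = FALSE)
    }
  } else {
    score_cols <- names(x)[vapply(x, is.numeric, logical(1))]
    if (length(score_cols) == 0L) stop("no numeric item columns found", call. = FALSE)
    bad <- vapply(x[score_cols], function(v) any(v < 1 | v > 5 | v != round(v)), logical(1))
    if (any(bad)) {
      stop("scores outside 1..5 in item(s): ",
           paste(score_cols[bad], collapse = ", "), call. = FALSE)
    }
    items <- tibble::tibble(
      item = score_cols,
      mean = unname(vapply(x[score_cols], mean, numeric(1))),
      sd = unname(vapply(x[score_cols], stats::sd, numeric(1))),
      n = nrow(x)
    )
  }
  structure(list(
    items = items,
    total = mean(items$mean),
    single_respondent = !is.na(items$n[1]) && items$n[1] == 1L
  ), class = "mecfes_quest")
}

#' @export
print.mecfes_quest <- function(x, ...) {
  cat("QUEST device-subscale summary\n")
  for (i in seq_len(nrow(x$items))) {
    r <- x$items[i, ]
    cat(sprintf("  %-14s %.2f%s\n", r$item, r$mean,
                if (is.na(r$sd)) "" else sprintf(" (SD %.2f)", r$sd)))
  }
  cat(sprintf("  total score: %.2f\n", x$total))
  if (isTRUE(x$single_respondent)) cat("  (single respondent: SDs undefined)\n")
  invisible(x)
}

#' Generate a synthetic IPPA cohort with a target mean change
#'
#' Draws, per participant, 1-7 problem items with integer importance and
#' difficulty ratings on the 1-5 grids, and reduces (or raises) the follow-up
#' difficulty stochastically so that the expected mean change equals
#' `effect`. Importance is uniform on 1-5 for `|effect| <= 12` and upweighted
#' toward 5 above that (a uniform importance caps the attainable expected
#' change at 12; the absolute ceiling is 20).
#'
#' @param n Number of participants (>= 2).
#' @param effect Target expected mean change score, in `[-20, 20]`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A tibble with one row per participant: `id`, `n_items`, `pre`,
#'   `fu`, `change`, and a list-column `items` of the underlying ratings.
#' @export
make_synthetic_cohort <- function(n, effect = 4.6, seed = 1L) {
  stopifnot(n >= 2L)
  if (abs(effect) > 20) {
    stop("|effect| > 20 is unattainable under IPPA scoring", call. = FALSE)
  }
  sgn <- sign(effect)
  ae <- abs(effect)
  if (ae <= 12) {
    w <- 0
    q <- ae / 12
  } else {
    w <- (ae / 4 - 3) / 2   # probability of forcing importance to 5
    q <- 1
  }
  with_seed(seed, {
    participants <- purrr::map(seq_len(n), function(i) {
      k <- sample.int(7L, 1L)
      imp <- ifelse(stats::runif(k) < w, 5L, sample.int(5L, k, replace = TRUE))
      delta <- stats::rbinom(k, 4L, q)
      if (sgn >= 0) {
        d_pre <- vapply(delta, function(d) resample_int(seq.int(1L + d, 5L)), integer(1))
        d_fu <- d_pre - delta
      } else {
        d_pre <- vapply(delta, function(d) resample_int(seq.int(1L, 5L - d)), integer(1))
        d_fu <- d_pre + delta
      }
      items <- tibble::tibble(importance = as.integer(imp),
                              difficulty_baseline = as.integer(d_pre),
                              difficulty_followup = as.integer(d_fu))
      tibble::tibble(
        id = sprintf("P%03d", i), n_items = k,
        pre = ippa_score(items, "baseline"),
        fu = ippa_score(items, "followup"),
        items = list(items)
      )
    })
    out <- dplyr::bind_rows(participants)
    out$change <- ippa_change(out$pre, out$fu)
    out[, c("id", "n_items", "pre", "fu", "change", "items")]
  })
}

#' @noRd
resample_int <- function(v) v[sample.int(length(v), 1L)]
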