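# Attentional-blink (RSVP) scoring and recall-1-back working-memory scoring.
#
# The attentional blink is the reduced probability of reporting a second
# target (T2) presented 200-500 ms after a first (T1) in a rapid serial
# visual presentation stream. Only trials with a correct T1 report enter the
# analysis (a correct T1 implies T1 was processed). The T2|T1 report function
# over the eight lags shows lag-1 sparing, a minimum around lags 2-3, and a
# recovery to an asymptote by lags 7-8.

#' T1-conditioned T2 report function
#'
#' For each person x task x lag, the proportion of correct T2 reports among
#' trials with a correct T1 report. Lags with no qualifying trial are
#' returned as missing (with a warning); a person with zero T1-correct trials
#' anywhere yields an all-missing curve.
#'
#' @param trials RSVP trial table with `person`, `task`, `lag` (1..8),
#'   `t1_correct`, `t2_correct` (0/1).
#' @return A tibble per person x task x lag: `n_lag` (trials at the lag),
#'   `n_t1` (T1-correct among them), `p_t2` (T2|T1 proportion, `NA` when
#'   `n_t1 = 0`).
#' @export
t2_given_t1_curve <- function(trials) {
  check_columns(
    trials, c("person", "task", "lag", "t1_correct", "t2_correct"), "trials"
  )
  stopifnot(all(trials$lag %in% 1:8))
  out <- trials |>
    dplyr::group_by(.data$person, .data$task, .data$lag) |>
    dplyr::summarise(
      n_lag = dplyr::n(),
      n_t1 = sum(.data$t1_correct == 1),
      p_t2 = if (sum(.data$t1_correct == 1) > 0) {
        mean(.data$t2_correct[.data$t1_correct == 1])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  if (any(is.na(out$p_t2))) {
    warn("some person x task x lag cells have no T1-correct trials; p_t2 is missing there")
  }
  out
}

#' Attentional-blink magnitude from a report function
#'
#' Collapses lags 2 and 3 into the blink minimum and lags 7 and 8 into the
#' asymptotic maximum, then returns `max - min`. Collapsing pools trials
#' (counts-weighted proportion), not an unweighted mean of the two per-lag
#' proportions, so unequal per-lag counts after T1 conditioning are handled
#' correctly. The magnitude may be negative (no flooring at zero), which
#' keeps reliability analyses unbiased.
#'
#' @param curve Output of [t2_given_t1_curve()] (any subset of persons/tasks).
#' @return A tibble per person x task: `collapsed_min`, `collapsed_max`,
#'   `ab_magnitude`, `t1_accuracy` (overall T1-correct proportion). Cells
#'   with any of lags 2, 3, 7, 8 missing get a missing magnitude and
#'   `complete = FALSE`.
#' @export
ab_magnitude <- function(curve) {
  check_columns(curve, c("person", "task", "lag", "n_lag", "n_t1", "p_t2"), "curve")
  pool <- function(p, n) {
    if (any(is.na(p)) || sum(n) == 0) NA_real_ else sum(p * n) / sum(n)
  }
  curve |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::summarise(
      collapsed_min = pool(
        .data$p_t2[.data$lag %in% 2:3], .data$n_t1[.data$lag %in% 2:3]
      ),
      collapsed_max = pool(
        .data$p_t2[.data$lag %in% 7:8], .data$n_t1[.data$lag %in% 7:8]
      ),
      t1_accuracy = sum(.data$n_t1) / sum(.data$n_lag),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ab_magnitude = .data$collapsed_max - .data$collapsed_min,
      complete = !is.na(.data$ab_magnitude)
    )
}

#' Score an RSVP task end to end
#'
#' Convenience wrapper: [t2_given_t1_curve()] then [ab_magnitude()].
#'
#' @inheritParams t2_given_t1_curve
#' @return The per-person magnitude tibble (see [ab_magnitude()]).
#' @export
ab_score <- function(trials) {
  ab_magnitude(t2_given_t1_curve(trials))
}

#' Bootstrap confidence band for the across-person median report function
#'
#' Percentile bootstrap over persons: persons are resampled with replacement
#' and the per-lag median of the per-person T2|T1 proportions recomputed.
#' Mirrors the usual display of an attentional-blink curve as the median
#' report function with a bootstrapped confidence band.
#'
#' @param trials RSVP trial table (see [t2_given_t1_curve()]); at least 10
#'   persons.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level (e.g. 0.99 for a 99% band).
#' @param seed Optional integer seed.
#' @return A tibble per task x lag: `median_p`, `lower`, `upper`.
#' @export
ab_curve_ci <- function(trials, n_boot = 1000, level = 0.99, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  curve <- t2_given_t1_curve(trials)
  persons <- unique(curve$person)
  if (length(persons) < 10) abort("need at least 10 persons for a bootstrap band")
  per_task <- split(curve, curve$task)
  purrr::map_dfr(per_task, function(cv) {
    wide <- cv |>
      dplyr::select("person", "lag", "p_t2") |>
      tidyr::pivot_wider(names_from = "lag", values_from = "p_t2") |>
      dplyr::arrange(.data$person)
    mat <- as.matrix(wide[, -1, drop = FALSE])
    lags <- as.integer(colnames(mat))
    obs <- unname(apply(mat, 2, median, na.rm = TRUE))
    boot <- replicate(n_boot, {
      idx <- sample(nrow(mat), replace = TRUE)
      apply(mat[idx, , drop = FALSE], 2, median, na.rm = TRUE)
    })
    alpha <- (1 - level) / 2
    tibble::tibble(
      task = cv$task[1],
      lag = lags,
      median_p = obs,
      lower = unname(apply(boot, 1, ms_quantile, probs = alpha)),
      upper = unname(apply(boot, 1, ms_quantile, probs = 1 - alpha))
    )
  })
}

#' Partial-credit working-memory score
#'
#' Recall-1-back tasks are scored with partial credit: the overall proportion
#' of correct responses over all stimulus displays of the test block, rather
#' than all-or-none scoring of runs.
#'
#' @param trials Recall-1-back table with `person`, `task`, `correct` (0/1).
#' @return A tibble per person x task: `partial_credit`, `n_displays`.
#'   Empty cells yield a missing score with a warning.
#' @export
wmc_partial_credit <- function(trials) {
  check_columns(trials, c("person", "task", "correct"), "trials")
  out <- trials |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::summarise(
      partial_credit = if (dplyr::n() > 0) mean(.data$correct) else NA_real_,
      n_displays = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_displays == 0)) warn("empty test block: partial credit is missing")
  out
}
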