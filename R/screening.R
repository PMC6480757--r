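# Trial-level screening: warm-up removal, post-error exclusion, and
# liberal-Tukey / 200 ms extreme-value exclusion, applied per person x task,
# with a report of exclusion proportions.

#' Drop warm-up trials
#'
#' Removes trials flagged as warm-ups (unanalyzed lead-in trials at the start
#' of each block), preserving row order.
#'
#' @param trials Trial table with an `is_warmup` logical column.
#' @return The table without warm-up rows. Warns if nothing remains.
#' @export
drop_warmups <- function(trials) {
  check_columns(trials, "is_warmup", "trials")
  out <- dplyr::filter(trials, !.data$is_warmup)
  if (nrow(out) == 0 && nrow(trials) > 0) {
    warn("all trials are flagged as warm-ups; returning an empty table")
  }
  out
}

#' Liberal Tukey extreme-value mask
#'
#' Flags response times more extreme than three times the interquartile range
#' above the third quartile or below the first quartile, or faster than the
#' 200 ms anticipation floor. Quartiles use the package-wide type-7
#' convention and are computed on the vector as given, so the caller controls
#' the reference set (per person x task, warm-up-free).
#'
#' @param rts Response times in ms (>= 4 values; quartiles are unstable
#'   below that).
#' @param k Fence multiplier (default 3, the "liberal" criterion; 1.5 would
#'   be the classical fence).
#' @param floor_ms Anticipation floor in ms (default 200).
#' @return Logical mask, `TRUE` = extreme.
#' @export
tukey_extreme_mask <- function(rts, k = 3, floor_ms = 200) {
  if (length(rts) < 4) {
    abort(sprintf(
      "need at least 4 trials to compute stable quartiles, got %d", length(rts)
    ))
  }
  q <- ms_quantile(rts, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  rts > q[2] + k * iqr | rts < q[1] - k * iqr | rts < floor_ms
}

#' Post-error trial mask
#'
#' Flags each trial whose immediately preceding trial (by presentation index,
#' within the same person x task x block) was an error, because post-error
#' slowing and related adjustments contaminate such responses. Adjacency is
#' defined on the original presentation indices: trial `t` is post-error iff
#' the trial with index `t - 1` is present in the table and was an error.
#' An error trial can itself be post-error. The first trial of a block is
#' never flagged, and once a post-error trial has been removed its successor
#' does not inherit the flag (index `t - 1` is then absent), so screening is
#' idempotent.
#'
#' @param trials Trial table with `person`, `task`, `block`, `trial`,
#'   `accuracy`.
#' @return Logical mask aligned with the rows of `trials`.
#' @export
post_error_mask <- function(trials) {
  check_columns(trials, c("person", "task", "block", "trial", "accuracy"), "trials")
  trials |>
    dplyr::group_by(.data$person, .data$task, .data$block) |>
    dplyr::mutate(
      .prev_err = (.data$trial - 1) %in% .data$trial[.data$accuracy == 0]
    ) |>
    dplyr::ungroup() |>
    dplyr::pull(".prev_err")
}

#' Screen a trial table
#'
#' Applies the package's exclusion rules per person x task: post-error trials
#' are removed first, then extreme values ([tukey_extreme_mask()]) are
#' detected on the post-error-free trials. Warm-ups must already be dropped
#' ([drop_warmups()]). Error trials themselves are retained (they carry the
#' error-rate information); only their successors are excluded.
#'
#' @param trials Warm-up-free trial table (`person`, `task`, `block`, `trial`,
#'   `rt_ms`, `accuracy`).
#' @return A list of class `screened_trials`: `$trials`, the retained rows;
#'   `$report`, a tibble per person x task with `n_total` (warm-up-free),
#'   `prop_post_error`, `prop_extreme` (both relative to `n_total`),
#'   `n_retained`, `n_retained_correct`, and `usable` (FALSE when no correct
#'   trial survives, flagging the cell for downstream exclusion).
#' @export
screen_trials <- function(trials) {
  check_columns(
    trials, c("person", "task", "block", "trial", "rt_ms", "accuracy"),
    "trials"
  )
  if ("is_warmup" %in% names(trials) && any(trials$is_warmup)) {
    abort("drop warm-ups with drop_warmups() before screening")
  }
  pe <- post_error_mask(trials)
  kept <- trials[!pe, , drop = FALSE]
  kept <- kept |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::mutate(
      .extreme = if (dplyr::n() >= 4) {
        tukey_extreme_mask(.data$rt_ms)
      } else {
        rep(FALSE, dplyr::n())
      }
    ) |>
    dplyr::ungroup()

  totals <- trials |>
    dplyr::count(.data$person, .data$task, name = "n_total")
  pe_counts <- trials[pe, , drop = FALSE] |>
    dplyr::count(.data$person, .data$task, name = "n_post_error")
  ex_counts <- kept |>
    dplyr::filter(.data$.extreme) |>
    dplyr::count(.data$person, .data$task, name = "n_extreme")
  retained <- kept |>
    dplyr::filter(!.data$.extreme) |>
    dplyr::select(-".extreme")
  ret_counts <- retained |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::summarise(
      n_retained = dplyr::n(),
      n_retained_correct = sum(.data$accuracy == 1),
      .groups = "drop"
    )
  report <- totals |>
    dplyr::left_join(pe_counts, by = c("person", "task")) |>
    dplyr::left_join(ex_counts, by = c("person", "task")) |>
    dplyr::left_join(ret_counts, by = c("person", "task")) |>
    dplyr::mutate(
      dplyr::across(
        c("n_post_error", "n_extreme", "n_retained", "n_retained_correct"),
        ~ dplyr::coalesce(.x, 0L)
      ),
      prop_post_error = .data$n_post_error / .data$n_total,
      prop_extreme = .data$n_extreme / .data$n_total,
      usable = .data$n_retained_correct > 0
    ) |>
    dplyr::select(
      "person", "task", "n_total", "n_post_error", "n_extreme",
      "prop_post_error", "prop_extreme", "n_retained",
      "n_retained_correct", "usable"
    )
  out <- list(trials = retained, report = report)
  class(out) <- "screened_trials"
  out
}

#' @export
print.screened_trials <- function(x, ...) {
  cat(sprintf(
    "Screened trials: %d rows retained across %d person x task cells\n",
    nrow(x$trials), nrow(x$report)
  ))
  cat(sprintf(
    "  mean excluded: post-error %.3f, extreme %.3f\n",
    mean(x$report$prop_post_error), mean(x$report$prop_extreme)
  ))
  invisible(x)
}

#' Summarise a screening report across persons (descriptives-table analog)
#'
#' Mean and SD across persons of the exclusion proportions, by task.
#'
#' @param x A `screened_trials` object.
#' @return A tibble per task with `post_err_m`, `post_err_sd`, `extreme_m`,
#'   `extreme_sd`.
#' @export
screening_summary <- function(x) {
  stopifnot(inherits(x, "screened_trials"))
  x$report |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(
      post_err_m = mean(.data$prop_post_error),
      post_err_sd = sd(.data$prop_post_error),
      extreme_m = mean(.data$prop_extreme),
      extreme_sd = sd(.data$prop_extreme),
      .groups = "drop"
    )
}
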