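# Worst-performance-rule RT-band analyses and correlations of speed scores
# with criterion composites, with Fisher-z confidence intervals and
# attenuation correction.

#' Partition response times into RT bands
#'
#' Per person x task, sorts the correct-trial RTs ascending and partitions
#' them into `k` contiguous bands of near-equal size, then takes the median
#' of each band. Band input deliberately skips extreme-value screening (the
#' band analysis is meant to see the slow tail); only warm-ups and error
#' trials are excluded upstream. When the trial count is not a multiple of
#' `k`, the remainder is distributed one-per-band from the last (slowest)
#' band backwards, so the slow bands keep the most trials and the band median
#' discards at least the few most extreme values.
#'
#' @param trials Warm-up-free trial table (`person`, `task`, `rt_ms`,
#'   `accuracy`); error trials are dropped internally.
#' @param k Number of bands (default 20, i.e. 5% steps).
#' @return A tibble per person x task x band: `band` (1 = fastest),
#'   `band_median` (ms), `n_in_band`. Cells with fewer than `k` correct
#'   trials are omitted with a warning.
#' @export
rt_bands <- function(trials, k = 20) {
  check_columns(trials, c("person", "task", "rt_ms", "accuracy"), "trials")
  stopifnot(k >= 2)
  correct <- dplyr::filter(trials, .data$accuracy == 1)
  too_few <- correct |>
    dplyr::count(.data$person, .data$task) |>
    dplyr::filter(.data$n < k)
  if (nrow(too_few) > 0) {
    warn(sprintf(
      "%d person x task cell(s) have fewer than %d correct trials and are omitted",
      nrow(too_few), k
    ))
  }
  correct |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::filter(dplyr::n() >= k) |>
    dplyr::group_modify(function(d, key) {
      rts <- sort(d$rt_ms)
      n <- length(rts)
      if (n < k) {
        return(tibble::tibble(
          band = integer(0), band_median = numeric(0), n_in_band = integer(0)
        ))
      }
      base_size <- n %/% k
      rem <- n %% k
      # bands k, k-1, ..., k-rem+1 get one extra trial each
      sizes <- rep(base_size, k)
      if (rem > 0) sizes[(k - rem + 1):k] <- base_size + 1L
      band_id <- rep(seq_len(k), times = sizes)
      tibble::tibble(
        band = seq_len(k),
        band_median = vapply(
          split(rts, band_id), median, numeric(1), USE.NAMES = FALSE
        ),
        n_in_band = sizes
      )
    }) |>
    dplyr::ungroup()
}

#' Criterion composite from standardized indicators
#'
#' z-standardizes each indicator across persons and averages the available
#' indicators per person. Persons missing every indicator get a missing
#' composite.
#'
#' @param indicators A tibble with a `person` column and one numeric column
#'   per indicator.
#' @return A tibble with `person` and `composite`.
#' @export
criterion_composite <- function(indicators) {
  check_columns(indicators, "person", "indicators")
  vars <- setdiff(names(indicators), "person")
  if (length(vars) < 1) abort("need at least one indicator column")
  z <- indicators |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(vars),
      ~ (.x - mean(.x, na.rm = TRUE)) / sd(.x, na.rm = TRUE)
    ))
  tibble::tibble(
    person = z$person,
    composite = rowMeans(as.matrix(z[, vars, drop = FALSE]), na.rm = TRUE)
  ) |>
    dplyr::mutate(composite = ifelse(is.nan(.data$composite), NA_real_, .data$composite))
}

#' Correlate two person-level scores
#'
#' Pearson correlation on pairwise-complete observations, optionally after
#' winsorizing both vectors, with a 95% Fisher-z confidence interval.
#'
#' @param x,y Numeric vectors aligned on persons (>= 10 complete pairs).
#' @param winsorize_frac Fraction winsorized per side before correlating
#'   (`NULL` = none).
#' @param level Confidence level.
#' @return A one-row tibble: `r`, `ci_lower`, `ci_upper`, `n`. Zero variance
#'   in either vector yields missing values with a `reason`.
#' @export
correlate_scores <- function(x, y, winsorize_frac = NULL, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 10) {
    abort(sprintf("need at least 10 complete pairs, got %d", length(x)))
  }
  if (!is.null(winsorize_frac)) {
    x <- winsorize(x, winsorize_frac)
    y <- winsorize(y, winsorize_frac)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(
      r = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
      n = length(x), reason = "zero_variance"
    ))
  }
  r <- cor(x, y)
  ci <- fisher_ci(r, length(x), level = level)
  tibble::tibble(
    r = r, ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
    n = length(x), reason = NA_character_
  )
}

#' Correct a correlation for attenuation by unreliability
#'
#' Classical disattenuation `r / sqrt(rel_x * rel_y)`, a lightweight observed
#' stand-in for a latent-variable correlation. The result is clipped to
#' `[-1, 1]`; clipping is flagged because it signals that the observed
#' correlation exceeds what the stated reliabilities allow.
#'
#' @param r Observed correlation.
#' @param rel_x,rel_y Reliabilities in `(0, 1]`.
#' @return A one-row tibble: `r_disattenuated`, `clipped`.
#' @export
disattenuate <- function(r, rel_x, rel_y) {
  if (rel_x <= 0 || rel_y <= 0 || rel_x > 1 || rel_y > 1) {
    abort("reliabilities must lie in (0, 1]")
  }
  raw <- r / sqrt(rel_x * rel_y)
  tibble::tibble(
    r_disattenuated = pmin(pmax(raw, -1), 1),
    clipped = abs(raw) > 1
  )
}

#' Band-by-band correlation trajectory
#'
#' Correlates each RT band's median (per task) with a person-level criterion,
#' yielding the 20-point trajectory used to assess the worst performance
#' rule: if the criterion is driven by attentional lapses (the slow tail),
#' the absolute correlation grows with band index; if it is driven by overall
#' position of the RT distribution, the trajectory is flat.
#'
#' @param bands Output of [rt_bands()].
#' @param criterion A tibble with `person` and `composite` (e.g. from
#'   [criterion_composite()]).
#' @param winsorize_frac Passed to [correlate_scores()].
#' @return A tibble per task x band: `r`, `ci_lower`, `ci_upper`, `n`.
#' @export
band_trajectory <- function(bands, criterion, winsorize_frac = NULL) {
  check_columns(bands, c("person", "task", "band", "band_median"), "bands")
  check_columns(criterion, c("person", "composite"), "criterion")
  bands |>
    dplyr::inner_join(criterion, by = "person") |>
    dplyr::group_by(.data$task, .data$band) |>
    dplyr::group_modify(function(d, key) {
      correlate_scores(
        d$band_median, d$composite,
        winsorize_frac = winsorize_frac
      )
    }) |>
    dplyr::ungroup()
}

#' Correlate every score column with a criterion
#'
#' Long-format relation report: one row per (task, score, criterion).
#'
#' @param scores Score tibble from [score_battery()] (`person`, `task`, plus
#'   score columns).
#' @param criteria Named list of criterion tibbles (`person`, `composite`),
#'   e.g. `list(wmc = ..., ab = ...)`.
#' @param winsorize_frac Passed to [correlate_scores()].
#' @return A tibble: `task`, `score`, `criterion`, `r`, `ci_lower`,
#'   `ci_upper`, `n`.
#' @export
relation_report <- function(scores, criteria, winsorize_frac = 0.025) {
  check_columns(scores, c("person", "task"), "scores")
  stopifnot(is.list(criteria), !is.null(names(criteria)))
  score_cols <- setdiff(names(scores), c("person", "task", "n_trials_used"))
  purrr::map_dfr(names(criteria), function(cn) {
    crit <- criteria[[cn]]
    joined <- dplyr::inner_join(scores, crit, by = "person")
    joined |>
      dplyr::group_by(.data$task) |>
      dplyr::group_modify(function(d, key) {
        purrr::map_dfr(score_cols, function(sc) {
          res <- correlate_scores(
            d[[sc]], d$composite,
            winsorize_frac = winsorize_frac
          )
          res$score <- sc
          res
        })
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(criterion = cn) |>
      dplyr::select(
        "task", "score", "criterion", "r", "ci_lower", "ci_upper", "n"
      )
  })
}
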