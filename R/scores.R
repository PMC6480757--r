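# Person x task battery of single speed scores: reciprocal speed, central
# tendency, equally-spaced quantiles, variability, error scores, and
# cross-person winsorization for the correlational analyses.

#' Mean reciprocal speed
#'
#' Averages reciprocal response times, `mean(1000 / rt_ms)`, giving responses
#' per second. This is the score that corresponds most closely to how
#' paper-and-pencil speed tests are scored (number correct per unit time).
#' By Jensen's inequality it is at least `1000 / mean(rt_ms)`, with equality
#' only for constant RTs.
#'
#' @param rts Correct, screened response times (ms).
#' @return Speed in 1/s, or `NA` (with a warning) for empty input.
#' @export
reciprocal_speed <- function(rts) {
  if (length(rts) == 0) {
    warn("no trials: reciprocal speed is missing")
    return(NA_real_)
  }
  mean(1000 / rts)
}

#' Central-tendency scores
#'
#' Mean RT, median RT (robust to slow extremes), and mean of natural-log RT.
#'
#' @param rts Correct, screened response times (ms).
#' @return A tibble row with `m_rt`, `mdn_rt` (ms), `m_logrt` (log-ms).
#' @export
central_tendency <- function(rts) {
  if (length(rts) == 0) {
    warn("no trials: central-tendency scores are missing")
    return(tibble::tibble(m_rt = NA_real_, mdn_rt = NA_real_, m_logrt = NA_real_))
  }
  tibble::tibble(
    m_rt = mean(rts),
    mdn_rt = ms_quantile(rts, 0.5),
    m_logrt = mean(base::log(rts))
  )
}

#' Five equally-spaced RT quantiles
#'
#' Quantiles at p = .20, .40, .60, .80, 1.00 by the package-wide type-7
#' convention; the 1.00 quantile is the maximum of the retained trials.
#' These slice the RT distribution so that the validity of specific portions
#' (e.g. the slow tail, cf. the worst performance rule) can be tested.
#'
#' @param rts Correct, screened response times (ms); at least 5 trials.
#' @return A tibble row `q20`..`q100` (ms), all-`NA` below 5 trials.
#' @export
quantile_scores <- function(rts) {
  if (length(rts) < 5) {
    warn("fewer than 5 trials: quantile scores are missing")
    return(tibble::tibble(
      q20 = NA_real_, q40 = NA_real_, q60 = NA_real_,
      q80 = NA_real_, q100 = NA_real_
    ))
  }
  q <- ms_quantile(rts, c(0.2, 0.4, 0.6, 0.8, 1.0))
  tibble::tibble(q20 = q[1], q40 = q[2], q60 = q[3], q80 = q[4], q100 = q[5])
}

#' Within-person variability scores
#'
#' Sample standard deviation (n - 1 denominator), natural log of the sample
#' variance, and the interquartile range (type-7 quartiles); the IQR is the
#' outlier-robust member of the trio. Degenerate (zero-variance) input yields
#' `SD = IQR = 0` with a missing log-variance.
#'
#' @param rts Correct, screened response times (ms); at least 4 trials.
#' @return A tibble row with `sd_rt` (ms), `logv_rt` (log ms^2), `iqr_rt` (ms).
#' @export
variability_scores <- function(rts) {
  if (length(rts) < 4) {
    warn("fewer than 4 trials: variability scores are missing")
    return(tibble::tibble(sd_rt = NA_real_, logv_rt = NA_real_, iqr_rt = NA_real_))
  }
  v <- var(rts)
  q <- ms_quantile(rts, c(0.25, 0.75))
  tibble::tibble(
    sd_rt = sqrt(v),
    logv_rt = if (v > 0) base::log(v) else NA_real_,
    iqr_rt = q[2] - q[1]
  )
}

#' Error-rate scores
#'
#' Proportion of errors over all screened trials (errors are retained in the
#' accuracy denominator) and its probit transformation, which normalizes the
#' heavily skewed error distribution. Boundary rates (0 errors are common in
#' easy tasks) are kept finite with the `(e + 0.5) / (n + 1)` adjustment
#' before applying the standard-normal quantile function.
#'
#' @param n_err Number of errors.
#' @param n_total Total screened trials (>= 1).
#' @return A tibble row with `error_rate`, `probit_error`.
#' @export
error_scores <- function(n_err, n_total) {
  stopifnot(n_total >= 1, n_err >= 0, n_err <= n_total)
  tibble::tibble(
    error_rate = n_err / n_total,
    probit_error = qnorm((n_err + 0.5) / (n_total + 1))
  )
}

#' Winsorize a score across persons
#'
#' Clamps the `ceiling(frac * n)` most extreme values on each side to the
#' nearest retained order statistic, symmetric at both tails. Used on every
#' score, per task, before correlational analyses so that a few extreme
#' persons cannot dominate a Pearson correlation. Idempotent. Missing values
#' are ignored and returned unchanged.
#'
#' @param x Numeric vector (one score across persons).
#' @param frac Fraction to clamp per side (default 0.025).
#' @return `x` with the extreme values clamped.
#' @export
winsorize <- function(x, frac = 0.025) {
  stopifnot(frac >= 0, frac < 0.5)
  ok <- which(!is.na(x))
  n <- length(ok)
  if (n == 0 || frac == 0) {
    return(x)
  }
  k <- ceiling(frac * n)
  if (2 * k >= n) {
    return(x)
  }
  srt <- sort(x[ok])
  lo <- srt[k + 1]
  hi <- srt[n - k]
  x[ok] <- pmin(pmax(x[ok], lo), hi)
  x
}

#' Score a screened trial battery
#'
#' Computes the full battery of single scores per person x task. All RT-based
#' scores use correct retained trials only; the error scores use all retained
#' trials (errors stay in the denominator).
#'
#' @param trials Screened trial table (`person`, `task`, `rt_ms`, `accuracy`),
#'   e.g. the `$trials` element of [screen_trials()]. A `screened_trials`
#'   object is also accepted.
#' @param winsorize_frac If non-`NULL`, each score column is winsorized across
#'   persons within task at this fraction per side (default `NULL`: raw
#'   scores; pass 0.025 before correlational analyses).
#' @return A tibble, one row per person x task, with `speed_1overrt`, `m_rt`,
#'   `mdn_rt`, `m_logrt`, `q20`..`q100`, `sd_rt`, `logv_rt`, `iqr_rt`,
#'   `error_rate`, `probit_error`, `n_trials_used` (correct retained trials).
#' @export
score_battery <- function(trials, winsorize_frac = NULL) {
  if (inherits(trials, "screened_trials")) trials <- trials$trials
  check_columns(trials, c("person", "task", "rt_ms", "accuracy"), "trials")
  scores <- trials |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::group_modify(function(d, key) {
      rts <- d$rt_ms[d$accuracy == 1]
      out <- dplyr::bind_cols(
        tibble::tibble(
          speed_1overrt = if (length(rts)) mean(1000 / rts) else NA_real_
        ),
        suppressWarnings(central_tendency(rts)),
        suppressWarnings(quantile_scores(rts)),
        suppressWarnings(variability_scores(rts)),
        error_scores(sum(d$accuracy == 0), nrow(d))
      )
      out$n_trials_used <- length(rts)
      out
    }) |>
    dplyr::ungroup()
  if (!is.null(winsorize_frac)) {
    score_cols <- setdiff(names(scores), c("person", "task", "n_trials_used"))
    scores <- scores |>
      dplyr::group_by(.data$task) |>
      dplyr::mutate(dplyr::across(
        dplyr::all_of(score_cols),
        ~ winsorize(.x, frac = winsorize_frac)
      )) |>
      dplyr::ungroup()
  }
  scores
}
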