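# broom-style tidiers for fitted objects.

#' Tidy an ex-Gaussian fit
#'
#' @param x An `exgauss_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`mu`, `sigma`, `tau`),
#'   columns `term` and `estimate` (ms).
#' @method tidy exgauss_fit
#' @export
tidy.exgauss_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma", "tau"),
    estimate = c(x$mu, x$sigma, x$tau)
  )
}

#' Glance at an ex-Gaussian fit
#'
#' @param x An `exgauss_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `loglik`, `n`, `converged`, `method`, plus the
#'   implied distribution mean `mu + tau` and standard deviation
#'   `sqrt(sigma^2 + tau^2)` (ms).
#' @method glance exgauss_fit
#' @export
glance.exgauss_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n = x$n,
    converged = x$converged,
    method = x$method,
    implied_mean = x$mu + x$tau,
    implied_sd = sqrt(x$sigma^2 + x$tau^2)
  )
}

#' Tidy a screening result
#'
#' @param x A `screened_trials` object.
#' @param ... Unused.
#' @return The per person x task screening report tibble.
#' @method tidy screened_trials
#' @export
tidy.screened_trials <- function(x, ...) {
  x$report
}

#' Glance at a screening result
#'
#' @param x A `screened_trials` object.
#' @param ... Unused.
#' @return One-row tibble with overall counts and mean exclusion proportions.
#' @method glance screened_trials
#' @export
glance.screened_trials <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$report),
    n_retained = nrow(x$trials),
    mean_prop_post_error = mean(x$report$prop_post_error),
    mean_prop_extreme = mean(x$report$prop_extreme)
  )
}
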