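# Ex-Gaussian distribution: density, CDF, quantiles, random draws, and two
# per-person estimators (maximum likelihood and a two-step kernel/bootstrap
# procedure), plus a quantile-based fit diagnostic across persons.
#
# The ex-Gaussian is the convolution of a normal component (mu, sigma) with an
# exponential component (tau). mu and sigma capture the location and spread of
# the distribution body; tau captures the slow right tail. All parameters are
# in milliseconds here, matching the trial tables.

# Stable evaluation of g(u) = u^2/2 + log(Phi(u)). The direct form loses all
# precision for u << 0 (the u^2/2 and log Phi terms cancel to ~15 digits and
# beyond), which happens whenever sigma/tau is large; the asymptotic Mills
# expansion takes over there.
log_phi_plus_half_usq <- function(u) {
  out <- numeric(length(u))
  direct <- u > -6
  out[direct] <- u[direct]^2 / 2 + pnorm(u[direct], log.p = TRUE)
  if (any(!direct)) {
    v <- u[!direct]
    out[!direct] <- -base::log(-v) - 0.5 * base::log(2 * pi) +
      log1p(-1 / v^2 + 3 / v^4)
  }
  out
}

check_exg_params <- function(mu, sigma, tau) {
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(tau)) {
    abort("ex-Gaussian parameters must be finite")
  }
  if (sigma <= 0 || tau <= 0) {
    abort("ex-Gaussian parameters require sigma > 0 and tau > 0")
  }
  invisible(NULL)
}

#' Ex-Gaussian density
#'
#' Density of the convolution of a `Normal(mu, sigma)` with an
#' `Exponential(tau)`:
#' `f(t) = (1/tau) exp((mu - t)/tau + sigma^2/(2 tau^2)) Phi((t - mu)/sigma - sigma/tau)`.
#' Evaluated in log space so that small `tau` (near-Gaussian data) does not
#' overflow the exponential prefactor.
#'
#' @param x Evaluation points (ms).
#' @param mu,sigma,tau Parameters; `sigma > 0`, `tau > 0` (ms).
#' @param log Return log density?
#' @return Numeric vector of (log) densities.
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exg_params(mu, sigma, tau)
  # With z = (x - mu)/sigma and u = z - sigma/tau, the exponent
  # (mu - x)/tau + sigma^2/(2 tau^2) equals u^2/2 - z^2/2, so
  # log f = -log(tau) - z^2/2 + [u^2/2 + log Phi(u)], the bracket evaluated
  # by the stable helper. The tau -> 0 limit is the Gaussian density.
  z <- (x - mu) / sigma
  u <- z - sigma / tau
  lf <- -base::log(tau) - z^2 / 2 + log_phi_plus_half_usq(u)
  if (log) lf else exp(lf)
}

#' Ex-Gaussian cumulative distribution function
#'
#' `F(t) = Phi((t - mu)/sigma) - exp((mu - t)/tau + sigma^2/(2 tau^2)) Phi((t - mu)/sigma - sigma/tau)`,
#' with the second term computed in log space.
#'
#' @inheritParams dexgauss
#' @param q Quantiles (ms).
#' @return Numeric vector of probabilities.
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  check_exg_params(mu, sigma, tau)
  z <- (q - mu) / sigma
  u <- z - sigma / tau
  p <- pnorm(z) - exp(-z^2 / 2 + log_phi_plus_half_usq(u))
  pmin(pmax(p, 0), 1)
}

#' Ex-Gaussian quantile function
#'
#' Inverts the CDF by bisection to an absolute tolerance of 1e-6 ms.
#'
#' @inheritParams dexgauss
#' @param p Probabilities in `(0, 1)`.
#' @return Numeric vector of quantiles (ms).
#' @export
qexgauss <- function(p, mu, sigma, tau) {
  check_exg_params(mu, sigma, tau)
  stopifnot(all(p > 0 & p < 1))
  vapply(p, function(pp) {
    lo <- mu - 10 * sigma
    hi <- mu + 10 * sigma + 50 * tau
    while (pexgauss(lo, mu, sigma, tau) > pp) lo <- lo - 10 * (sigma + tau)
    while (pexgauss(hi, mu, sigma, tau) < pp) hi <- hi + 10 * (sigma + tau)
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (pexgauss(mid, mu, sigma, tau) < pp) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Ex-Gaussian random draws
#'
#' @inheritParams dexgauss
#' @param n Number of draws.
#' @return Numeric vector of draws (ms).
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exg_params(mu, sigma, tau)
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

# Moment (method-of-moments) starting values. Solves the ex-Gaussian moment
# identities mean = mu + tau, var = sigma^2 + tau^2, skew = 2 tau^3 / var^(3/2).
exg_moment_start <- function(rts) {
  m <- mean(rts)
  s <- sd(rts)
  skew <- mean((rts - m)^3) / s^3
  tau0 <- s * (pmax(skew, 0.01) / 2)^(1 / 3)
  tau0 <- min(tau0, 0.95 * s)
  sigma0 <- sqrt(pmax(s^2 - tau0^2, (0.05 * s)^2))
  c(mu = m - tau0, sigma = sigma0, tau = tau0)
}

#' Fit an ex-Gaussian by maximum likelihood
#'
#' The reference estimator of the package. Maximizes the summed log density
#' over `(mu, sigma, tau)` with positivity of `sigma` and `tau` enforced by a
#' log parameterization, using derivative-free Nelder-Mead with five starts
#' (moment estimates plus jittered restarts) and a relative log-likelihood
#' tolerance of 1e-8.
#'
#' @param rts Correct, screened response times (ms); at least 40 trials.
#' @param n_starts Number of optimizer starts (first is the moment estimate).
#' @param min_n Minimum trial count accepted.
#' @return An object of class `exgauss_fit`: a list with `mu`, `sigma`, `tau`
#'   (ms), `loglik`, `converged`, `n`, and `method = "mle"`.
#' @seealso [fit_exgauss_two_step()], [exgauss_fit_quality()]
#' @export
fit_exgauss_mle <- function(rts, n_starts = 5, min_n = 40) {
  rts <- rts[is.finite(rts)]
  if (length(rts) < min_n) {
    abort(sprintf(
      "ex-Gaussian fit needs at least %d trials, got %d", min_n, length(rts)
    ))
  }
  negll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    tau <- exp(par[3])
    -sum(dexgauss(rts, mu, sigma, tau, log = TRUE))
  }
  start0 <- exg_moment_start(rts)
  best <- NULL
  any_converged <- FALSE
  for (k in seq_len(n_starts)) {
    jit <- if (k == 1) c(0, 0, 0) else c(
      runif(1, -0.2, 0.2) * start0["sigma"],
      runif(1, -0.3, 0.3),
      runif(1, -0.3, 0.3)
    )
    par0 <- c(
      start0["mu"] + jit[1],
      base::log(start0["sigma"]) + jit[2],
      base::log(start0["tau"]) + jit[3]
    )
    res <- tryCatch(
      optim(par0, negll,
        method = "Nelder-Mead",
        control = list(reltol = 1e-8, maxit = 2000)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) abort("ex-Gaussian MLE failed at every start")
  out <- list(
    mu = unname(best$par[1]),
    sigma = unname(exp(best$par[2])),
    tau = unname(exp(best$par[3])),
    loglik = -best$value,
    converged = any_converged && best$convergence == 0,
    n = length(rts),
    method = "mle"
  )
  class(out) <- "exgauss_fit"
  out
}

# Mode offset of the ex-Gaussian: the distance between mu and the density
# mode of ExGauss(mu, sigma, tau). Scale-free in (sigma, tau), located by
# golden-section search on the density of ExGauss(0, sigma, tau).
exg_mode_offset <- function(sigma, tau) {
  stats::optimize(
    function(t) -dexgauss(t, 0, sigma, tau),
    interval = c(-sigma, 5 * sigma)
  )$minimum
}

#' Fit an ex-Gaussian with a two-step kernel/bootstrap estimator
#'
#' Companion estimator to the maximum-likelihood reference. Step 1 locates
#' the density mode with a Gaussian kernel estimate and converts it into an
#' estimate of the Gaussian component location: the ex-Gaussian mode sits to
#' the right of `mu` by an offset determined by `(sigma, tau)`, which is
#' evaluated at the moment estimates (skewness identity for `tau`, variance
#' identity for `sigma`) and subtracted from the kernel mode. Step 2 sets
#' `tau` as the mean over bootstrap resamples of `(resample mean - mu_hat)`
#' via the identity `mean = mu + tau`, floored at a small positive value,
#' and `sigma` is re-read from the variance identity. Discrepancies with the
#' MLE on real data are informative about tail behaviour and are reported,
#' not hidden.
#'
#' @inheritParams fit_exgauss_mle
#' @param n_boot Number of bootstrap resamples for the `tau` step (>= 100).
#' @param seed Optional integer seed for the bootstrap, for reproducibility.
#' @return An `exgauss_fit` object with `method = "two_step"` (no `loglik`
#'   maximization; `loglik` is evaluated at the estimate).
#' @export
fit_exgauss_two_step <- function(rts, n_boot = 200, min_n = 40, seed = NULL) {
  rts <- rts[is.finite(rts)]
  if (length(rts) < min_n) {
    abort(sprintf(
      "ex-Gaussian fit needs at least %d trials, got %d", min_n, length(rts)
    ))
  }
  if (n_boot < 100) abort("n_boot must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  dens <- density(rts, kernel = "gaussian")
  mode_hat <- dens$x[which.max(dens$y)]
  s <- sd(rts)
  start <- exg_moment_start(rts)
  mu_hat <- mode_hat - exg_mode_offset(start[["sigma"]], start[["tau"]])
  boot_means <- vapply(
    seq_len(n_boot),
    function(i) mean(sample(rts, replace = TRUE)),
    numeric(1)
  )
  tau_hat <- max(mean(boot_means) - mu_hat, 1e-3)
  sigma_hat <- sqrt(pmax(s^2 - tau_hat^2, (0.05 * s)^2))
  out <- list(
    mu = mu_hat,
    sigma = sigma_hat,
    tau = tau_hat,
    loglik = sum(dexgauss(rts, mu_hat, sigma_hat, tau_hat, log = TRUE)),
    converged = TRUE,
    n = length(rts),
    method = "two_step"
  )
  class(out) <- "exgauss_fit"
  out
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf(
    "Ex-Gaussian fit (%s): mu = %.1f ms, sigma = %.1f ms, tau = %.1f ms\n",
    x$method, x$mu, x$sigma, x$tau
  ))
  cat(sprintf(
    "  n = %d, loglik = %.2f, converged = %s\n",
    x$n, x$loglik, x$converged
  ))
  invisible(x)
}

#' Fit ex-Gaussian parameters for every person by task
#'
#' Maps [fit_exgauss_mle()] (or the two-step variant) over a screened trial
#' table, using correct trials only.
#'
#' @param trials Trial table with `person`, `task`, `rt_ms`, `accuracy`.
#' @param method `"mle"` or `"two_step"`.
#' @param min_n Minimum correct trials per person x task; cells below it are
#'   returned with missing parameters.
#' @param ... Passed on to the fitting function.
#' @return A tibble with one row per person x task: `mu`, `sigma`, `tau`,
#'   `loglik`, `converged`, `n`.
#' @export
fit_exgauss <- function(trials, method = c("mle", "two_step"), min_n = 40, ...) {
  method <- match.arg(method)
  check_columns(trials, c("person", "task", "rt_ms", "accuracy"), "trials")
  fitter <- switch(method,
    mle = function(x) fit_exgauss_mle(x, min_n = min_n),
    two_step = function(x) fit_exgauss_two_step(x, min_n = min_n, ...)
  )
  trials |>
    dplyr::filter(.data$accuracy == 1) |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n) {
        return(tibble::tibble(
          mu = NA_real_, sigma = NA_real_, tau = NA_real_,
          loglik = NA_real_, converged = FALSE, n = nrow(d)
        ))
      }
      f <- fitter(d$rt_ms)
      tibble::tibble(
        mu = f$mu, sigma = f$sigma, tau = f$tau,
        loglik = f$loglik, converged = f$converged, n = f$n
      )
    }) |>
    dplyr::ungroup()
}

#' Quantile-based fit diagnostic for ex-Gaussian parameter tables
#'
#' For each person, compares observed RT quantiles at 10, 25, 50, 75 and 90
#' per cent with the model-implied quantiles from the fitted parameters
#' (numeric CDF inversion). Across persons the diagnostic is the Pearson
#' correlation of observed with implied quantiles at each probability level;
#' on well-specified data these correlations are expected to be almost
#' perfect. With a single person the per-person root-mean-square quantile
#' discrepancy (ms) is reported instead.
#'
#' @param trials Screened trial table (`person`, `task`, `rt_ms`, `accuracy`).
#' @param params Parameter tibble from [fit_exgauss()] (person, task, mu,
#'   sigma, tau).
#' @param probs Probability levels for the check.
#' @return A tibble with one row per task x probability level: `r`
#'   (correlation across persons) and `n_persons`; or, for a single person,
#'   one row per task with `rms` in ms.
#' @export
exgauss_fit_quality <- function(trials, params,
                                probs = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  check_columns(trials, c("person", "task", "rt_ms", "accuracy"), "trials")
  check_columns(params, c("person", "task", "mu", "sigma", "tau"), "params")
  obs <- trials |>
    dplyr::filter(.data$accuracy == 1) |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::reframe(
      prob = probs,
      observed = ms_quantile(.data$rt_ms, probs)
    )
  imp <- params |>
    dplyr::filter(!is.na(.data$mu)) |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::reframe(
      prob = probs,
      implied = qexgauss(probs, .data$mu[1], .data$sigma[1], .data$tau[1])
    )
  both <- dplyr::inner_join(obs, imp, by = c("person", "task", "prob"))
  n_person <- dplyr::n_distinct(both$person)
  if (n_person < 2) {
    return(
      both |>
        dplyr::group_by(.data$task) |>
        dplyr::summarise(
          rms = sqrt(mean((.data$observed - .data$implied)^2)),
          .groups = "drop"
        )
    )
  }
  both |>
    dplyr::group_by(.data$task, .data$prob) |>
    dplyr::summarise(
      r = cor(.data$observed, .data$implied),
      n_persons = dplyr::n(),
      .groups = "drop"
    )
}
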