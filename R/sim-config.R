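# Configuration object for the synthetic trial-level generator. The defaults
# reproduce the design of a nine-task mental speed battery (3 task types x 3
# stimulus materials, two blocks of 60 analyzed trials plus two warm-ups per
# block), two RSVP attentional-blink tasks (3 blocks of 48 trials, lags 1-8
# balanced at 18 trials per lag), and three recall-1-back working-memory
# tasks (12 runs crossing memory loads 1-4 with 6, 9 or 12 updates, 108
# displays). Base RT parameters are graded by task-type complexity the way
# observed batteries are (Search fastest and least variable, Substitution
# slowest and most variable).

#' Default latent trait correlation matrix
#'
#' Correlations among the four person-level traits: `S` (general slowness),
#' `L` (attentional lapses), `W` (working-memory ability), `B` (blink
#' depth). The default encodes the qualitative structure such batteries
#' show: slowness and lapses go together, both run against working-memory
#' ability, and the blink is only weakly tied to speed.
#'
#' @return A 4 x 4 correlation matrix.
#' @export
default_latent_corr <- function() {
  traits <- c("S", "L", "W", "B")
  m <- matrix(c(
    1.00, 0.50, -0.45, 0.15,
    0.50, 1.00, -0.55, 0.20,
    -0.45, -0.55, 1.00, -0.25,
    0.15, 0.20, -0.25, 1.00
  ), 4, 4, dimnames = list(traits, traits))
  m
}

#' Default speed-task types with complexity-graded base parameters
#'
#' Three task types of increasing complexity: visual search (respond to one
#' target), string comparison (hold three elements briefly), and symbol
#' substitution (repeated look-up of nine mappings, with nine response
#' alternatives). Ex-Gaussian base parameters (ms) and diffusion base
#' parameters (seconds, scaling constant 0.1) grade upward with complexity
#' the way observed batteries do.
#'
#' @return A tibble, one row per task type.
#' @export
default_task_types <- function() {
  tibble::tibble(
    task_type = c("search", "comparison", "substitution"),
    complexity = c(0, 1, 2),
    mu0 = c(330, 750, 945),
    sigma0 = c(40, 103, 130),
    tau0 = c(68, 228, 312),
    v0 = c(0.40, 0.22, 0.18),
    a0 = c(0.093, 0.145, 0.160),
    ter0 = c(0.26, 0.55, 0.65),
    n_alternatives = c(2L, 2L, 9L)
  )
}

#' Default trait-to-parameter map coefficients
#'
#' @param ... Named overrides, e.g. `default_loadings(b_tau = 0)`.
#' @return Named list of loading coefficients (see [sim_config()]).
#' @export
default_loadings <- function(...) {
  base <- list(
    b_mu = 0.06, b_sigma = 0.25, b_tau = 0.28,
    b_v = 0.15, b_a = 0.15, b_ter = 0.08,
    b_err = 0.40, b_wmc = 0.90, b_p1 = 0.30,
    b_depth = 0.50
  )
  utils::modifyList(base, list(...))
}

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic generator into one validated object.
#' Person-level traits are a 4-variate standard normal: `S` (general
#' slowness), `L` (attentional lapses, feeding the exponential RT tail and
#' error rate), `W` (working-memory ability), `B` (attentional-blink depth),
#' correlated by `latent_corr`. Per-task RT parameters are deterministic
#' log-linear maps of the traits (positivity guaranteed), with coefficients
#' in `loadings`; the complexity grade `c` of the task type scales the `S`
#' effect on distribution position.
#'
#' @param n_persons Number of simulated persons.
#' @param task_types Tibble of task types (see `default_task_types()`):
#'   `task_type`, `complexity` (>= 0), ex-Gaussian base parameters `mu0`,
#'   `sigma0`, `tau0` (ms), diffusion base parameters `v0`, `a0`, `ter0`
#'   (seconds), `n_alternatives`.
#' @param materials Stimulus materials crossed with every task type.
#' @param n_blocks,trials_per_block,warmups_per_block Speed-task block design.
#' @param generator_mode `"exgauss"` (RT = Normal + Exponential, accuracy
#'   Bernoulli) or `"diffusion"` (two-boundary Wiener first passage).
#' @param latent_corr 4 x 4 correlation matrix over traits S, L, W, B; must
#'   be symmetric positive semi-definite with unit diagonal.
#' @param loadings Named list of trait-to-parameter map coefficients:
#'   `b_mu`, `b_sigma`, `b_tau` (ex-Gaussian), `b_v`, `b_a`, `b_ter`
#'   (diffusion), `b_err` (logit error rate on L), `b_wmc` (recall-1-back
#'   ability on W), `b_p1` (T1 accuracy on W), `b_depth` (logit blink depth
#'   on B).
#' @param error_model List: `p0` baseline error probability.
#' @param rsvp List: `tasks`, `n_blocks`, `trials_per_block`,
#'   `warmups_per_block`, `lags`, `p1` (baseline T1 accuracy), `q0` (baseline
#'   T2|T1), `depth` (baseline blink depth), `lag1_sparing` (fraction of the
#'   blink spared at lag 1).
#' @param n1back List: `tasks`, `loads`, `updates` (the full crossing defines
#'   the test block), `theta0` ability intercept, `beta_load` load slope.
#' @param ez_s Diffusion scaling constant used in diffusion mode.
#' @param dt Euler step of the Wiener simulator, seconds.
#' @param seed Master seed; per-person, per-task substreams are derived from
#'   it deterministically so subsets are reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 129,
                       task_types = default_task_types(),
                       materials = c("numbers", "letters", "symbols"),
                       n_blocks = 2,
                       trials_per_block = 60,
                       warmups_per_block = 2,
                       generator_mode = c("exgauss", "diffusion"),
                       latent_corr = default_latent_corr(),
                       loadings = default_loadings(),
                       error_model = list(p0 = 0.04),
                       rsvp = list(
                         tasks = c("rsvp_letters", "rsvp_digits"),
                         n_blocks = 3, trials_per_block = 48,
                         warmups_per_block = 1, lags = 1:8,
                         p1 = 0.85, q0 = 0.85, depth = 0.35,
                         lag1_sparing = 0.8
                       ),
                       n1back = list(
                         tasks = c("n1back_numbers", "n1back_letters", "n1back_symbols"),
                         loads = 1:4, updates = c(6, 9, 12),
                         theta0 = 1.8, beta_load = 0.35
                       ),
                       ez_s = 0.1,
                       dt = 1e-4,
                       seed = 1L) {
  generator_mode <- match.arg(generator_mode)
  stopifnot(
    n_persons >= 1, n_blocks >= 1, trials_per_block >= 1,
    warmups_per_block >= 0, ez_s > 0, dt > 0
  )
  check_columns(
    task_types,
    c("task_type", "complexity", "mu0", "sigma0", "tau0", "v0", "a0", "ter0"),
    "task_types"
  )
  if (any(task_types$complexity < 0)) abort("complexity must be >= 0")
  if (any(task_types$mu0 <= 0 | task_types$sigma0 <= 0 | task_types$tau0 <= 0 |
    task_types$v0 <= 0 | task_types$a0 <= 0 | task_types$ter0 <= 0)) {
    abort("all base RT parameters must be positive")
  }
  validate_latent_corr(latent_corr)
  probs <- c(
    error_model$p0, rsvp$p1, rsvp$q0, rsvp$depth, rsvp$lag1_sparing
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (!identical(sort(unique(rsvp$lags)), 1:8)) {
    abort("rsvp lags must cover 1..8")
  }
  out <- list(
    n_persons = as.integer(n_persons),
    task_types = task_types,
    materials = materials,
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    warmups_per_block = as.integer(warmups_per_block),
    generator_mode = generator_mode,
    latent_corr = latent_corr,
    loadings = loadings,
    error_model = error_model,
    rsvp = rsvp,
    n1back = n1back,
    ez_s = ez_s,
    dt = dt,
    seed = as.integer(seed)
  )
  class(out) <- "sim_config"
  out
}

validate_latent_corr <- function(m) {
  if (!is.matrix(m) || nrow(m) != 4 || ncol(m) != 4) {
    abort("latent_corr must be a 4 x 4 matrix over traits S, L, W, B")
  }
  if (max(abs(m - t(m))) > 1e-10) abort("latent_corr must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10) abort("latent_corr must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort(sprintf(
      "latent_corr is not positive semi-definite: smallest eigenvalue = %.6f",
      min(ev)
    ))
  }
  invisible(m)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d persons, %d speed tasks (%s mode), seed %d\n",
    x$n_persons,
    nrow(x$task_types) * length(x$materials),
    x$generator_mode, x$seed
  ))
  invisible(x)
}
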