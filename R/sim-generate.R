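# Trial-level generators: person truth, speed-task trials (ex-Gaussian or
# Wiener diffusion), RSVP attentional-blink trials, and recall-1-back
# displays, all reproducible from one master seed via deterministic
# per-person/per-task substreams.

# Blink-shaped T2|T1 report function over lags 1..8 for one person.
# lag 1: partially spared; lags 2-3: full blink depth; lags 4-6: linear
# recovery; lags 7-8: asymptote at baseline.
blink_curve <- function(q0, depth, lag1_sparing) {
  q <- c(
    q0 - (1 - lag1_sparing) * depth,
    q0 - depth, q0 - depth,
    q0 - 0.75 * depth, q0 - 0.5 * depth, q0 - 0.25 * depth,
    q0, q0
  )
  pmin(pmax(q, 0.02), 0.98)
}

#' Draw person-level ground truth
#'
#' Draws the four latent traits from a multivariate normal with the
#' configured correlation matrix and maps them deterministically onto
#' per-task RT parameters (log-linear maps, so positive parameters stay
#' positive), error rates (logistic in the lapse trait), recall-1-back
#' ability, and RSVP curve parameters. The map coefficients travel with the
#' output so recovery tests can reconstruct any link.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `person_truth`: `$traits` (tibble per person:
#'   `person`, `S`, `L`, `W`, `B`, `p_err`, `theta`, `p1`, `q0_t2`, `depth`),
#'   `$task_params` (tibble per person x speed task: `task`, `task_type`,
#'   `material`, `complexity`, `mu`, `sigma`, `tau` (ms), `v`, `a`, `ter`
#'   (s), `p_err`, `n_alternatives`), `$coefficients`, `$config`.
#' @export
draw_persons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "persons"))
  b <- config$loadings
  tr <- MASS::mvrnorm(
    config$n_persons,
    mu = rep(0, 4), Sigma = config$latent_corr
  )
  tr <- matrix(tr, ncol = 4)
  colnames(tr) <- c("S", "L", "W", "B")
  traits <- tibble::as_tibble(tr) |>
    dplyr::mutate(
      person = sprintf("p%03d", seq_len(config$n_persons)),
      p_err = plogis(qlogis(config$error_model$p0) + b$b_err * .data$L),
      theta = config$n1back$theta0 + b$b_wmc * .data$W,
      p1 = plogis(qlogis(config$rsvp$p1) + b$b_p1 * .data$W),
      q0_t2 = config$rsvp$q0,
      depth = plogis(qlogis(config$rsvp$depth) + b$b_depth * .data$B),
      .before = 1
    ) |>
    dplyr::relocate("person")
  tasks <- tidyr::expand_grid(
    config$task_types,
    material = config$materials
  ) |>
    dplyr::mutate(task = paste(.data$task_type, .data$material, sep = "_"))
  task_params <- tidyr::expand_grid(
    traits |>
      dplyr::select("person", "S", "L", "W", "p_err"),
    tasks
  ) |>
    dplyr::mutate(
      mu = .data$mu0 * exp(b$b_mu * (1 + .data$complexity) * .data$S),
      sigma = .data$sigma0 * exp(b$b_sigma * .data$S),
      tau = .data$tau0 * exp(b$b_tau * .data$L),
      v = .data$v0 * exp(-b$b_v * .data$S),
      a = .data$a0 * exp(-b$b_a * .data$W),
      ter = .data$ter0 * exp(b$b_ter * .data$S)
    ) |>
    dplyr::select(
      "person", "task", "task_type", "material", "complexity",
      "mu", "sigma", "tau", "v", "a", "ter", "p_err", "n_alternatives"
    )
  out <- list(
    traits = traits,
    task_params = task_params,
    coefficients = b,
    config = config
  )
  class(out) <- "person_truth"
  out
}

#' @export
print.person_truth <- function(x, ...) {
  cat(sprintf(
    "Person truth: %d persons x %d speed tasks (%s mode)\n",
    nrow(x$traits), dplyr::n_distinct(x$task_params$task),
    x$config$generator_mode
  ))
  invisible(x)
}

#' Simulate speed-task trials
#'
#' Generates the full battery of speed-task trials for every person. In
#' `exgauss` mode each RT is `Normal(mu_i, sigma_i) + Exponential(tau_i)`
#' with accuracy `Bernoulli(1 - p_err_i)`; in `diffusion` mode each trial is
#' a two-boundary Wiener first passage (unbiased start, Euler scheme, see
#' [simulate_wiener()]) with `rt = decision time + ter_i`, and accuracy given
#' by the absorbing boundary. RTs are floored at 1 ms. Each block starts
#' with flagged warm-up trials, and trial indices record presentation order
#' so post-error adjacency is meaningful.
#'
#' @param persons A `person_truth` object from [draw_persons()].
#' @param config The same [sim_config()]; defaults to the one embedded in
#'   `persons`.
#' @return A tibble: `person`, `task`, `task_type`, `material`, `block`,
#'   `trial` (within block, warm-ups first), `rt_ms`, `accuracy`,
#'   `is_warmup`, `n_alternatives`.
#' @export
simulate_speed_trials <- function(persons, config = persons$config) {
  stopifnot(inherits(persons, "person_truth"))
  n_analysis <- config$trials_per_block
  n_warm <- config$warmups_per_block
  per_block <- n_warm + n_analysis
  n_per_task <- config$n_blocks * per_block
  rows <- persons$task_params |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::group_modify(function(p, key) {
      set.seed(substream_seed(config$seed, "speed", key$person, key$task))
      if (config$generator_mode == "exgauss") {
        rt <- rnorm(n_per_task, p$mu, p$sigma) + rexp(n_per_task, 1 / p$tau)
        acc <- rbinom(n_per_task, 1, 1 - p$p_err)
      } else {
        w <- simulate_wiener(
          n_per_task, p$v, p$a, p$ter,
          s = config$ez_s, dt = config$dt
        )
        rt <- w$rt * 1000
        acc <- w$accuracy
      }
      tibble::tibble(
        task_type = p$task_type, material = p$material,
        block = rep(seq_len(config$n_blocks), each = per_block),
        trial = rep(seq_len(per_block), times = config$n_blocks),
        rt_ms = pmax(rt, 1),
        accuracy = acc,
        is_warmup = rep(
          c(rep(TRUE, n_warm), rep(FALSE, n_analysis)),
          times = config$n_blocks
        ),
        n_alternatives = p$n_alternatives
      )
    }) |>
    dplyr::ungroup()
  rows
}

#' Simulate RSVP attentional-blink trials
#'
#' For each person and RSVP task, generates blocks of trials with the T2 lag
#' balanced within block (with the default design, 3 blocks x 48 trials give
#' exactly 18 analysis trials per lag per task), plus flagged warm-up trials
#' with a random lag. T1 report is `Bernoulli(p1_i)`; conditional on a
#' correct T1, T2 report is `Bernoulli(q_i(lag))` where the per-person curve
#' `q_i` has lag-1 sparing, its minimum at lags 2-3 (baseline minus blink
#' depth `d_i`), and an asymptote at lags 7-8. After a T1 failure the T2
#' report probability is halved (such trials never enter the scored curve).
#'
#' @inheritParams simulate_speed_trials
#' @return A tibble: `person`, `task`, `block`, `trial`, `lag`, `t1_correct`,
#'   `t2_correct`, `is_warmup`.
#' @export
simulate_rsvp <- function(persons, config = persons$config) {
  stopifnot(inherits(persons, "person_truth"))
  rv <- config$rsvp
  per_lag_block <- rv$trials_per_block / length(rv$lags)
  if (per_lag_block != round(per_lag_block)) {
    abort("trials_per_block must be a multiple of the number of lags")
  }
  grid <- tidyr::expand_grid(
    person = persons$traits$person,
    task = rv$tasks
  )
  purrr::pmap_dfr(grid, function(person, task) {
    set.seed(substream_seed(config$seed, "rsvp", person, task))
    tr <- persons$traits[persons$traits$person == person, ]
    q <- blink_curve(tr$q0_t2, tr$depth, rv$lag1_sparing)
    purrr::map_dfr(seq_len(rv$n_blocks), function(bl) {
      lag_warm <- sample(rv$lags, rv$warmups_per_block, replace = TRUE)
      lag_main <- sample(rep(rv$lags, per_lag_block))
      lags <- c(lag_warm, lag_main)
      n <- length(lags)
      t1 <- rbinom(n, 1, tr$p1)
      p_t2 <- ifelse(t1 == 1, q[lags], 0.5 * q[lags])
      tibble::tibble(
        person = person, task = task, block = bl,
        trial = seq_len(n), lag = lags,
        t1_correct = t1,
        t2_correct = rbinom(n, 1, p_t2),
        is_warmup = c(
          rep(TRUE, rv$warmups_per_block),
          rep(FALSE, rv$trials_per_block)
        )
      )
    })
  })
}

#' Simulate recall-1-back displays
#'
#' For each person and task, the test block crosses every memory load with
#' every update count (12 runs with the default 4 loads x {6, 9, 12}
#' updates, for 108 displays), in randomized run order. Each display is
#' correct with probability `logistic(theta_i - beta_load * load)`.
#'
#' @inheritParams simulate_speed_trials
#' @return A tibble: `person`, `task`, `run`, `load`, `n_updates`,
#'   `display` (index within run), `correct`.
#' @export
simulate_n1back <- function(persons, config = persons$config) {
  stopifnot(inherits(persons, "person_truth"))
  nb <- config$n1back
  runs <- tidyr::expand_grid(load = nb$loads, n_updates = nb$updates)
  grid <- tidyr::expand_grid(
    person = persons$traits$person,
    task = nb$tasks
  )
  purrr::pmap_dfr(grid, function(person, task) {
    set.seed(substream_seed(config$seed, "n1back", person, task))
    theta <- persons$traits$theta[persons$traits$person == person]
    run_order <- runs[sample(nrow(runs)), ]
    purrr::map_dfr(seq_len(nrow(run_order)), function(r) {
      load <- run_order$load[r]
      u <- run_order$n_updates[r]
      tibble::tibble(
        person = person, task = task, run = r,
        load = load, n_updates = u,
        display = seq_len(u),
        correct = rbinom(u, 1, plogis(theta - nb$beta_load * load))
      )
    })
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper that draws persons and generates all three trial
#' tables.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_study`: `$persons` (ground truth),
#'   `$speed_trials`, `$rsvp_trials`, `$n1back_trials`.
#' @export
simulate_study <- function(config = sim_config()) {
  persons <- draw_persons(config)
  out <- list(
    persons = persons,
    speed_trials = simulate_speed_trials(persons, config),
    rsvp_trials = simulate_rsvp(persons, config),
    n1back_trials = simulate_n1back(persons, config)
  )
  class(out) <- "sim_study"
  out
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d persons; %d speed trials, %d RSVP trials, %d recall-1-back displays\n",
    nrow(x$persons$traits), nrow(x$speed_trials), nrow(x$rsvp_trials),
    nrow(x$n1back_trials)
  ))
  invisible(x)
}

#' Write a simulated study to delimited files
#'
#' Writes `speed_trials.csv`, `rsvp_trials.csv`, `n1back_trials.csv`, and the
#' ground-truth tables `truth_traits.csv` and `truth_task_params.csv` into a
#' directory.
#'
#' @param study A `sim_study` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$speed_trials, file.path(dir, "speed_trials.csv"),
    row.names = FALSE
  )
  utils::write.csv(study$rsvp_trials, file.path(dir, "rsvp_trials.csv"),
    row.names = FALSE
  )
  utils::write.csv(study$n1back_trials, file.path(dir, "n1back_trials.csv"),
    row.names = FALSE
  )
  utils::write.csv(study$persons$traits, file.path(dir, "truth_traits.csv"),
    row.names = FALSE
  )
  utils::write.csv(study$persons$task_params,
    file.path(dir, "truth_task_params.csv"),
    row.names = FALSE
  )
  invisible(dir)
}
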