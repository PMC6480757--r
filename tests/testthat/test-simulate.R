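# Synthetic generator: latent-trait structure, distributional identities,
# design counts, and reproducibility.

test_that("trait draws reproduce the latent correlation matrix", {
  # independence case
  cfg0 <- sim_config(n_persons = 2000, latent_corr = identity_corr(), seed = 5)
  tr0 <- draw_persons(cfg0)$traits
  emp0 <- cor(as.matrix(tr0[, c("S", "L", "W", "B")]))
  se <- 1 / sqrt(2000)
  expect_lt(max(abs(emp0[upper.tri(emp0)])), 3 * se)

  # a single planted correlation is recovered
  lc <- identity_corr()
  lc["S", "W"] <- lc["W", "S"] <- 0.6
  cfg1 <- sim_config(n_persons = 2000, latent_corr = lc, seed = 6)
  tr1 <- draw_persons(cfg1)$traits
  expect_lt(abs(cor(tr1$S, tr1$W) - 0.6), 0.05)

  # full default matrix within 0.05 everywhere
  cfg2 <- sim_config(n_persons = 2000, seed = 7)
  tr2 <- draw_persons(cfg2)$traits
  emp2 <- cor(as.matrix(tr2[, c("S", "L", "W", "B")]))
  expect_lt(max(abs(emp2 - default_latent_corr())), 0.05)
})

test_that("non-PSD latent correlation is rejected with the eigenvalue named", {
  bad <- matrix(c(
    1, 0.9, -0.9, 0,
    0.9, 1, 0.9, 0,
    -0.9, 0.9, 1, 0,
    0, 0, 0, 1
  ), 4, 4, dimnames = list(c("S", "L", "W", "B"), c("S", "L", "W", "B")))
  expect_error(
    sim_config(latent_corr = bad),
    "eigenvalue"
  )
})

test_that("zero tail loading makes tau identical across persons", {
  cfg <- tiny_config(n_persons = 30, loadings = default_loadings(b_tau = 0))
  tp <- draw_persons(cfg)$task_params
  expect_equal(tp$tau, rep(default_task_types()$tau0[1], nrow(tp)))
})

test_that("ex-Gaussian trials match the closed-form moments", {
  # one person, fixed parameters, no trait variation
  cfg <- tiny_config(
    n_persons = 1, n_blocks = 1, trials_per_block = 10000,
    warmups_per_block = 0,
    task_types = dplyr::mutate(
      default_task_types()[1, ],
      mu0 = 300, sigma0 = 30, tau0 = 70
    ),
    loadings = default_loadings(b_mu = 0, b_sigma = 0, b_tau = 0),
    seed = 3
  )
  tr <- simulate_speed_trials(draw_persons(cfg), cfg)
  expect_equal(nrow(tr), 10000)
  expect_lt(abs(mean(tr$rt_ms) - 370), 3)
  expect_lt(abs(sd(tr$rt_ms) - sqrt(30^2 + 70^2)), 3)
  # skewness identity 2 tau^3 / (sigma^2 + tau^2)^(3/2) = 0.797
  sk <- mean((tr$rt_ms - mean(tr$rt_ms))^3) / sd(tr$rt_ms)^3
  expect_lt(abs(sk - 2 * 70^3 / (30^2 + 70^2)^1.5), 0.15)
})

test_that("Wiener accuracy matches the closed-form absorption probability", {
  set.seed(42)
  w <- simulate_wiener(4000, v = 0.2, a = 0.12, ter = 0.25, dt = 1e-4)
  p_theory <- 1 / (1 + exp(-0.12 * 0.2 / 0.1^2))
  se <- sqrt(p_theory * (1 - p_theory) / 4000)
  expect_lt(abs(mean(w$accuracy) - p_theory), 3 * se)

  # zero drift: symmetric random walk
  w0 <- simulate_wiener(3000, v = 0, a = 0.1, ter = 0.2, dt = 1e-4)
  expect_lt(abs(mean(w0$accuracy) - 0.5), 3 * sqrt(0.25 / 3000))
})

test_that("same seed gives bit-identical tables; substreams are per-cell", {
  cfg <- tiny_config(n_persons = 4, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$speed_trials, s2$speed_trials)
  expect_identical(s1$rsvp_trials, s2$rsvp_trials)
  expect_identical(s1$n1back_trials, s2$n1back_trials)
  # regenerating a subset of persons reproduces their rows exactly
  p <- draw_persons(cfg)
  p_sub <- p
  p_sub$traits <- p$traits[2, ]
  p_sub$task_params <- p$task_params[p$task_params$person == p$traits$person[2], ]
  sub <- simulate_speed_trials(p_sub, cfg)
  full <- s1$speed_trials[s1$speed_trials$person == p$traits$person[2], ]
  expect_equal(as.data.frame(sub), as.data.frame(full))
})

test_that("RSVP design yields 18 analysis trials per lag per task", {
  cfg <- tiny_config(n_persons = 3, seed = 2)
  rsvp <- simulate_rsvp(draw_persons(cfg), cfg)
  counts <- rsvp |>
    dplyr::filter(!.data$is_warmup) |>
    dplyr::count(.data$person, .data$task, .data$lag)
  expect_true(all(counts$n == 18))
  per_task <- rsvp |>
    dplyr::filter(!.data$is_warmup) |>
    dplyr::count(.data$person, .data$task)
  expect_true(all(per_task$n == 144))
})

test_that("zero blink depth gives near-zero expected AB magnitude", {
  cfg <- sim_config(
    n_persons = 150,
    latent_corr = identity_corr(),
    rsvp = list(
      tasks = "rsvp_letters", n_blocks = 3, trials_per_block = 48,
      warmups_per_block = 1, lags = 1:8, p1 = 0.9, q0 = 0.9,
      depth = 0, lag1_sparing = 0.8
    ),
    loadings = default_loadings(b_depth = 0),
    seed = 21
  )
  ab <- ab_score(dplyr::filter(simulate_rsvp(draw_persons(cfg), cfg), !is_warmup))
  m <- mean(ab$ab_magnitude, na.rm = TRUE)
  se <- sd(ab$ab_magnitude, na.rm = TRUE) / sqrt(sum(!is.na(ab$ab_magnitude)))
  expect_lt(abs(m), 3 * se + 1e-8)
})

test_that("recall-1-back test block has 108 displays from the full crossing", {
  cfg <- tiny_config(n_persons = 2, seed = 4)
  nb <- simulate_n1back(draw_persons(cfg), cfg)
  counts <- dplyr::count(nb, person, task)
  expect_true(all(counts$n == 108))
  # 12 runs crossing 4 loads x {6, 9, 12} updates
  runs <- nb |> dplyr::distinct(person, task, run, load, n_updates)
  per_cell <- runs |> dplyr::count(person, task)
  expect_true(all(per_cell$n == 12))
  crossing <- runs |>
    dplyr::filter(person == person[1], task == task[1]) |>
    dplyr::count(load, n_updates)
  expect_equal(nrow(crossing), 12)
})

test_that("ability extremes drive partial credit to its limits", {
  cfg_hi <- tiny_config(
    n_persons = 3,
    n1back = list(
      tasks = "n1back_numbers", loads = 1:4, updates = c(6, 9, 12),
      theta0 = 50, beta_load = 0.35
    ),
    loadings = default_loadings(b_wmc = 0), seed = 8
  )
  nb_hi <- simulate_n1back(draw_persons(cfg_hi), cfg_hi)
  expect_true(all(wmc_partial_credit(nb_hi)$partial_credit == 1))

  cfg_coin <- tiny_config(
    n_persons = 60,
    n1back = list(
      tasks = "n1back_numbers", loads = 1:4, updates = c(6, 9, 12),
      theta0 = 0, beta_load = 0
    ),
    loadings = default_loadings(b_wmc = 0), seed = 9
  )
  nb_coin <- simulate_n1back(draw_persons(cfg_coin), cfg_coin)
  pc <- wmc_partial_credit(nb_coin)$partial_credit
  expect_lt(abs(mean(pc) - 0.5), 3 * sqrt(0.25 / (60 * 108)))
})
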