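# RT bands, criterion composites, correlations with CIs, disattenuation,
# and band trajectories.

test_that("band partition sizes follow the remainder rule", {
  tr <- make_trials(rt = sample(seq(250, 2000, length.out = 130)),
                    acc = rep(1, 130))
  bands <- rt_bands(tr, k = 20)
  expect_equal(nrow(bands), 20)
  expect_equal(sum(bands$n_in_band), 130)
  expect_equal(bands$n_in_band, c(rep(6L, 10), rep(7L, 10)))
  expect_true(all(diff(bands$band_median) >= 0))
})

test_that("singleton bands return the sorted values themselves", {
  tr <- make_trials(rt = sample(201:220), acc = rep(1, 20))
  bands <- rt_bands(tr, k = 20)
  expect_equal(bands$band_median, as.numeric(201:220))
})

test_that("bands use correct trials only and refuse tiny cells", {
  tr <- make_trials(rt = c(rep(300, 25), rep(9000, 5)),
                    acc = c(rep(1, 25), rep(0, 5)))
  bands <- rt_bands(tr, k = 20)
  expect_true(all(bands$band_median == 300))
  small <- make_trials(rt = rep(300, 10), acc = rep(1, 10))
  expect_warning(out <- rt_bands(small, k = 20), "fewer than 20")
  expect_equal(nrow(out), 0)
})

test_that("criterion composite standardizes and averages indicators", {
  ind <- tibble::tibble(person = sprintf("p%d", 1:20), a = rnorm(20))
  comp <- criterion_composite(ind)
  expect_equal(comp$composite, as.numeric(scale(ind$a)))
  # perfectly correlated indicators: composite correlates 1 with each
  ind2 <- tibble::tibble(person = ind$person, a = ind$a, b = 3 * ind$a + 5)
  comp2 <- criterion_composite(ind2)
  expect_equal(cor(comp2$composite, ind2$a), 1)
  expect_lt(abs(mean(comp2$composite)), 1e-10)
  expect_lte(sd(comp2$composite), 1 + 1e-10)
  # all-missing person propagates
  ind3 <- tibble::tibble(person = c("x", "y", "z"), a = c(1, NA, 2), b = c(2, NA, 4))
  expect_true(is.na(criterion_composite(ind3)$composite[2]))
})

test_that("correlation report gives exact limits and sign anti-symmetry", {
  x <- rnorm(30)
  self <- correlate_scores(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$ci_lower, 1)
  y <- rnorm(30)
  expect_equal(correlate_scores(x, -y)$r, -correlate_scores(x, y)$r)
  const <- correlate_scores(x, rep(1, 30))
  expect_true(is.na(const$r))
  expect_equal(const$reason, "zero_variance")
  expect_error(correlate_scores(x[1:5], y[1:5]), "at least 10")
})

test_that("Fisher-z intervals cover the null at roughly the nominal rate", {
  set.seed(40)
  covered <- vapply(1:200, function(i) {
    x <- rnorm(50)
    y <- rnorm(50)
    ci <- correlate_scores(x, y)
    ci$ci_lower <= 0 && ci$ci_upper >= 0
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})

test_that("disattenuation rescales, clips, and refuses bad reliabilities", {
  expect_equal(disattenuate(0.45, 0.81, 0.81)$r_disattenuated, 0.45 / 0.81)
  expect_equal(disattenuate(0.3, 1, 1)$r_disattenuated, 0.3)
  clip <- disattenuate(0.9, 0.5, 0.5)
  expect_equal(clip$r_disattenuated, 1)
  expect_true(clip$clipped)
  expect_error(disattenuate(0.5, 0, 0.8), "reliabilities")
  # disattenuated magnitude never below the raw magnitude
  for (r in c(-0.6, -0.1, 0.2, 0.7)) {
    expect_gte(abs(disattenuate(r, 0.8, 0.9)$r_disattenuated), abs(r))
  }
})

test_that("band trajectory separates tail-linked from position-linked criteria", {
  run_traj <- function(link, seed) {
    cfg <- sim_config(
      n_persons = 250,
      task_types = default_task_types()[1, ], materials = "numbers",
      n_blocks = 2, trials_per_block = 120,
      latent_corr = identity_corr(),
      loadings = if (link == "tau") {
        default_loadings(b_mu = 0, b_sigma = 0)
      } else {
        default_loadings(b_mu = 0.15, b_sigma = 0, b_tau = 0)
      },
      seed = seed
    )
    p <- draw_persons(cfg)
    tr <- drop_warmups(simulate_speed_trials(p, cfg))
    bands <- rt_bands(tr, k = 20)
    crit <- tibble::tibble(
      person = p$traits$person,
      composite = if (link == "tau") p$traits$L else p$traits$S
    )
    band_trajectory(bands, crit)
  }
  tj_tau <- run_traj("tau", 50)
  expect_gt(abs(tj_tau$r[tj_tau$band == 20]), abs(tj_tau$r[tj_tau$band == 1]) + 0.2)
  tj_mu <- run_traj("mu", 51)
  expect_lt(abs(tj_mu$r[tj_mu$band == 20] - tj_mu$r[tj_mu$band == 1]), 0.2)
  # zero-loading criterion: everything near zero
  set.seed(52)
  cfg0 <- tiny_config(n_persons = 200, n_blocks = 2, trials_per_block = 60)
  p0 <- draw_persons(cfg0)
  tr0 <- drop_warmups(simulate_speed_trials(p0, cfg0))
  b0 <- rt_bands(tr0, k = 20)
  crit0 <- tibble::tibble(person = p0$traits$person, composite = rnorm(200))
  tj0 <- band_trajectory(b0, crit0)
  expect_lt(max(abs(tj0$r)), 0.25)
})

test_that("quantile-score ordering is consistent with the band trajectory", {
  cfg <- sim_config(
    n_persons = 250, task_types = default_task_types()[1, ],
    materials = "numbers", n_blocks = 2, trials_per_block = 60,
    latent_corr = identity_corr(),
    loadings = default_loadings(b_mu = 0, b_sigma = 0),
    seed = 53
  )
  p <- draw_persons(cfg)
  tr <- drop_warmups(simulate_speed_trials(p, cfg))
  crit <- tibble::tibble(person = p$traits$person, composite = p$traits$L)
  sc <- score_battery(screen_trials(tr)) |> dplyr::inner_join(crit, by = "person")
  r_q <- vapply(
    c("q20", "q40", "q60", "q80", "q100"),
    function(q) cor(sc[[q]], sc$composite, use = "complete.obs"),
    numeric(1)
  )
  # tail-linked criterion: slow quantiles more predictive than fast ones
  expect_gt(r_q["q100"], r_q["q20"])
  bands <- rt_bands(tr, k = 20)
  tj <- band_trajectory(bands, crit)
  expect_gt(tj$r[tj$band == 20], tj$r[tj$band == 1])
})

test_that("relation report is long-format with one row per score and criterion", {
  set.seed(54)
  trs <- dplyr::bind_rows(lapply(sprintf("p%02d", 1:25), function(pp) {
    make_trials(rt = rexgauss(80, 300, 30, 70), acc = rbinom(80, 1, 0.95),
                person = pp)
  }))
  sc <- score_battery(screen_trials(trs))
  crit <- list(
    wmc = tibble::tibble(person = sprintf("p%02d", 1:25), composite = rnorm(25))
  )
  rep <- relation_report(sc, crit, winsorize_frac = 0.025)
  expect_setequal(
    unique(rep$score),
    setdiff(names(sc), c("person", "task", "n_trials_used"))
  )
  expect_true(all(rep$criterion == "wmc"))
  expect_true(all(rep$ci_lower <= rep$r & rep$r <= rep$ci_upper, na.rm = TRUE))
})
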