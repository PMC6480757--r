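# Screening rules: warm-up removal, Tukey/floor extreme detection, post-error
# exclusion, their composition, and idempotence.

test_that("warm-up trials are dropped, preserving order", {
  tr <- make_trials(
    rt = c(400, 410, seq(300, 359)),
    acc = rep(1, 62),
    warmup = c(TRUE, TRUE, rep(FALSE, 60))
  )
  out <- drop_warmups(tr)
  expect_equal(nrow(out), 60)
  expect_equal(out$trial, 3:62)

  no_warm <- make_trials(rt = c(300, 310), acc = c(1, 1))
  expect_identical(drop_warmups(no_warm), no_warm)

  all_warm <- make_trials(rt = c(300, 310), acc = c(1, 1), warmup = c(TRUE, TRUE))
  expect_warning(out2 <- drop_warmups(all_warm), "warm-ups")
  expect_equal(nrow(out2), 0)
})

test_that("Tukey fence and 200 ms floor flag the right trials", {
  # hand computation: sorted {300,310,320,330,340,5000}; type-7 quartiles
  # Q1 = 312.5, Q3 = 337.5, IQR = 25 -> fences [237.5, 412.5]
  rts <- c(300, 310, 320, 330, 340, 5000)
  expect_equal(tukey_extreme_mask(rts), c(rep(FALSE, 5), TRUE))

  # constant vector: IQR = 0, only the floor can fire
  expect_equal(tukey_extreme_mask(rep(300, 6)), rep(FALSE, 6))
  expect_equal(tukey_extreme_mask(rep(150, 6)), rep(TRUE, 6))

  # anything below 200 ms is flagged regardless of the fences
  rts2 <- c(150, 300, 310, 320, 330)
  expect_true(tukey_extreme_mask(rts2)[1])

  expect_error(tukey_extreme_mask(c(300, 310, 320)), "at least 4")
})

test_that("post-error mask follows presentation order within blocks", {
  tr <- make_trials(rt = rep(300, 4), acc = c(1, 0, 1, 1))
  expect_equal(post_error_mask(tr), c(FALSE, FALSE, TRUE, FALSE))

  # an error trial can itself be post-error
  tr2 <- make_trials(rt = rep(300, 4), acc = c(1, 0, 0, 1))
  expect_equal(post_error_mask(tr2), c(FALSE, FALSE, TRUE, TRUE))

  # an error on the last trial of a block does not leak into the next block
  tr3 <- dplyr::bind_rows(
    make_trials(rt = rep(300, 3), acc = c(1, 1, 0), block = 1),
    make_trials(rt = rep(300, 3), acc = c(1, 1, 1), block = 2)
  )
  expect_equal(post_error_mask(tr3), rep(FALSE, 6))

  expect_equal(
    post_error_mask(make_trials(rt = rep(300, 5), acc = rep(1, 5))),
    rep(FALSE, 5)
  )
})

test_that("screen_trials matches a hand trace of both rules", {
  # 10 trials; error at trial 2 removes trial 3 (rt 310) as post-error.
  # Remaining nine RTs {300,305,315,320,325,330,335,340,5000}:
  # Q1 = 315, Q3 = 335, IQR = 20 -> upper fence 395 -> 5000 flagged.
  tr <- make_trials(
    rt = c(300, 305, 310, 315, 320, 325, 330, 335, 340, 5000),
    acc = c(1, 0, 1, 1, 1, 1, 1, 1, 1, 1)
  )
  sc <- screen_trials(tr)
  expect_equal(sc$report$n_total, 10)
  expect_equal(sc$report$n_post_error, 1)
  expect_equal(sc$report$n_extreme, 1)
  expect_equal(sc$report$prop_post_error, 0.1)
  expect_equal(sc$report$prop_extreme, 0.1)
  expect_equal(sc$report$n_retained, 8)
  expect_equal(sort(sc$trials$rt_ms), c(300, 305, 315, 320, 325, 330, 335, 340))
  expect_true(sc$report$usable)

  # no errors, no outliers: identity
  clean <- make_trials(rt = seq(300, 345, by = 5), acc = rep(1, 10))
  sc2 <- screen_trials(clean)
  expect_equal(nrow(sc2$trials), 10)
  expect_equal(sc2$report$prop_post_error + sc2$report$prop_extreme, 0)
})

test_that("cells with no surviving correct trial are flagged unusable", {
  tr <- make_trials(rt = c(300, 310, 320, 330), acc = c(0, 0, 0, 0))
  sc <- screen_trials(tr)
  expect_false(sc$report$usable)
})

test_that("screening is idempotent", {
  set.seed(10)
  tr <- make_trials(
    rt = rexgauss(200, 300, 30, 70),
    acc = rbinom(200, 1, 0.9)
  )
  sc1 <- screen_trials(tr)
  sc2 <- screen_trials(sc1$trials)
  expect_equal(nrow(sc2$trials), nrow(sc1$trials))
  expect_equal(sc2$report$n_post_error, 0L)
})

test_that("screening one person alone equals their slice of a joint screen", {
  set.seed(11)
  tr <- dplyr::bind_rows(lapply(c("pA", "pB", "pC"), function(p) {
    make_trials(
      rt = rexgauss(80, 300, 30, 70) + ifelse(p == "pC", 800, 0),
      acc = rbinom(80, 1, 0.93), person = p
    )
  }))
  joint <- screen_trials(tr)$trials
  alone <- screen_trials(tr[tr$person == "pA", ])$trials
  expect_equal(
    as.data.frame(alone),
    as.data.frame(joint[joint$person == "pA", ])
  )
})

test_that("screening refuses tables that still contain warm-ups", {
  tr <- make_trials(rt = rep(300, 5), acc = rep(1, 5),
                    warmup = c(TRUE, rep(FALSE, 4)))
  expect_error(screen_trials(tr), "warm-ups")
})

test_that("tidiers expose the report", {
  tr <- make_trials(rt = seq(300, 345, by = 5), acc = rep(1, 10))
  sc <- screen_trials(tr)
  expect_identical(tidy(sc), sc$report)
  g <- glance(sc)
  expect_equal(g$n_retained, 10)
})
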