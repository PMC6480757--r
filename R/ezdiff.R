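# EZ diffusion model: closed-form inversion of three observed moments
# (proportion correct, mean and variance of correct RT) into drift rate v,
# boundary separation a, and non-decision time Ter, the matching forward
# mapping, an edge correction for perfect accuracy, and a two-boundary Wiener
# first-passage simulator used as an independent oracle in tests.
#
# All EZ computations are in seconds; the diffusion scaling constant s fixes
# the (arbitrary) evidence scale and defaults to the conventional 0.1.

#' Invert EZ diffusion moments into diffusion parameters
#'
#' Closed-form inversion. With `L = log(Pc/(1 - Pc))`:
#' `x = L (L Pc^2 - L Pc + Pc - 0.5) / VRT`, `v = sign(Pc - 0.5) s x^(1/4)`,
#' `a = s^2 L / v`; then with `y = -v a / s^2` the mean decision time is
#' `MDT = (a / 2v) (1 - e^y) / (1 + e^y)` and `Ter = MRT - MDT`.
#'
#' @param pc Proportion correct, strictly inside `(0, 1)` and not exactly 0.5
#'   (drift is unidentified at chance). Apply [edge_correct()] first for
#'   perfect scores.
#' @param mrt Mean of correct RTs, seconds.
#' @param vrt Variance of correct RTs, seconds squared; must be positive.
#' @param s Diffusion scaling constant (default 0.1).
#' @return A tibble row: `v` (evidence/s), `a`, `ter` (s), `s`,
#'   `ter_warning` (TRUE when `ter < 0`, a possible model violation).
#' @export
ez_inverse <- function(pc, mrt, vrt, s = 0.1) {
  stopifnot(length(pc) == 1, length(mrt) == 1, length(vrt) == 1)
  if (!is.finite(pc) || pc <= 0 || pc >= 1) {
    abort("pc must lie strictly inside (0, 1); use edge_correct() for 0/1 scores")
  }
  if (pc == 0.5) abort("drift unidentified at chance (pc = 0.5 exactly)")
  if (!is.finite(vrt) || vrt <= 0) abort("vrt must be positive")
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- -v * a / s^2
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  ter <- mrt - mdt
  tibble::tibble(
    v = v, a = a, ter = ter, s = s,
    ter_warning = ter < 0
  )
}

#' Forward EZ diffusion mapping (parameters to moments)
#'
#' Exact inverse of [ez_inverse()] by construction: with `y = -v a / s^2`,
#' `Pc = 1 / (1 + e^y)`, `MRT = Ter + (a / 2v)(1 - e^y)/(1 + e^y)`, and `VRT`
#' recovered from the drift relation `x = (v/s)^4`.
#'
#' @param v Drift rate (nonzero; at `v = 0` accuracy is at chance and the
#'   moments are not invertible).
#' @param a Boundary separation (> 0).
#' @param ter Non-decision time, seconds.
#' @param s Diffusion scaling constant.
#' @return A tibble row: `pc`, `mrt`, `vrt`.
#' @export
ez_forward <- function(v, a, ter, s = 0.1) {
  stopifnot(a > 0, s > 0)
  if (v == 0) {
    abort("v = 0: accuracy is at chance (pc = 0.5) and the mapping is not invertible")
  }
  y <- -v * a / s^2
  pc <- 1 / (1 + exp(y))
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  L <- qlogis(pc)
  vrt <- L * (L * pc^2 - L * pc + pc - 0.5) / (v / s)^4
  tibble::tibble(pc = pc, mrt = ter + mdt, vrt = vrt)
}

#' Edge correction for perfect or zero accuracy
#'
#' Perfect per-person accuracy occurs routinely in easy speed tasks, and the
#' EZ inversion is undefined at `Pc = 1`. Replaces `Pc = 1` by `1 - 1/(2n)`
#' and `Pc = 0` by `1/(2n)`; intermediate proportions (including exactly 0.5,
#' which the caller must handle) pass through unchanged.
#'
#' @param n_correct Number of correct trials.
#' @param n_total Total trial count (>= 1).
#' @return Corrected proportion correct.
#' @export
edge_correct <- function(n_correct, n_total) {
  stopifnot(n_total >= 1, n_correct >= 0, n_correct <= n_total)
  pc <- n_correct / n_total
  if (pc == 1) {
    1 - 1 / (2 * n_total)
  } else if (pc == 0) {
    1 / (2 * n_total)
  } else {
    pc
  }
}

#' Simulate two-boundary Wiener first-passage trials
#'
#' Euler-Maruyama simulation of the drift-diffusion decision process:
#' evidence starts unbiased at `a/2` and evolves as
#' `dX = v dt + s sqrt(dt) dW` until it is absorbed at `a` (correct) or 0
#' (error); `ter` is added to the decision time. The discrete step induces a
#' small boundary-overshoot bias of order `sqrt(dt)`, so recovery checks use
#' `dt` of 0.05-0.1 ms. Used throughout the package as the independent oracle
#' for the EZ closed forms.
#'
#' @param n Number of trials.
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param ter Non-decision time, seconds.
#' @param s Diffusion scaling constant.
#' @param dt Euler step, seconds (default 1e-4, i.e. 0.1 ms).
#' @param max_t Absorbing-time cap, seconds; unabsorbed trials (essentially
#'   impossible at sane parameters) are assigned the boundary they are
#'   nearest to at the cap.
#' @param chunk Steps simulated per vectorized block (performance knob only;
#'   the trajectory law is unaffected).
#' @return A tibble with `rt` (s) and `accuracy` (1 = upper/correct boundary).
#' @export
simulate_wiener <- function(n, v, a, ter, s = 0.1, dt = 1e-4, max_t = 20,
                            chunk = 1024) {
  stopifnot(a > 0, s > 0, dt > 0, n >= 1)
  x <- rep(a / 2, n)
  t_dec <- rep(NA_real_, n)
  acc <- integer(n)
  active <- seq_len(n)
  max_steps <- ceiling(max_t / dt)
  steps_done <- 0
  mu_step <- v * dt
  sd_step <- s * sqrt(dt)
  while (length(active) > 0 && steps_done < max_steps) {
    m <- min(chunk, max_steps - steps_done)
    na <- length(active)
    inc <- matrix(rnorm(m * na, mu_step, sd_step), nrow = m)
    paths <- matrix(apply(inc, 2, cumsum), nrow = m)
    paths <- sweep(paths, 2, x[active], "+")
    hit <- paths >= a | paths <= 0
    crossed <- colSums(hit) > 0
    if (any(crossed)) {
      first <- max.col(t(hit[, crossed, drop = FALSE]), ties.method = "first")
      cols <- which(crossed)
      endpoint <- paths[cbind(first, cols)]
      idx <- active[cols]
      t_dec[idx] <- (steps_done + first) * dt
      acc[idx] <- as.integer(endpoint >= a)
    }
    if (any(!crossed)) x[active[!crossed]] <- paths[m, !crossed]
    active <- active[!crossed]
    steps_done <- steps_done + m
  }
  if (length(active) > 0) {
    t_dec[active] <- max_t
    acc[active] <- as.integer(x[active] >= a / 2)
  }
  tibble::tibble(rt = t_dec + ter, accuracy = acc)
}

#' Fit EZ diffusion parameters for every person by task
#'
#' Computes the three EZ moments per person x task from a screened trial table
#' (accuracy over all screened trials, RT mean and variance over correct
#' trials, converted from ms to seconds) and applies [ez_inverse()] with
#' [edge_correct()]. Tasks with more than two response alternatives cannot be
#' described by a two-boundary decision process; they are refused with reason
#' `"more_than_two_alternatives"`, and chance-level cells with reason
#' `"pc_at_chance"`.
#'
#' @param trials Screened trial table (`person`, `task`, `rt_ms`, `accuracy`).
#' @param s Diffusion scaling constant.
#' @param two_choice_tasks Optional character vector naming the tasks that are
#'   two-alternative; if supplied, other tasks are refused. If `NULL`
#'   (default) and the table has an `n_alternatives` column, tasks with
#'   `n_alternatives > 2` are refused; otherwise all tasks are fitted.
#' @param min_n Minimum trial count per cell.
#' @return A tibble per person x task: `v`, `a`, `ter` (s), `pc`, `mrt`,
#'   `vrt`, `n`, `reason` (`NA` when fitted).
#' @export
fit_ezdiff <- function(trials, s = 0.1, two_choice_tasks = NULL, min_n = 20) {
  check_columns(trials, c("person", "task", "rt_ms", "accuracy"), "trials")
  refuse_task <- function(task, d) {
    if (!is.null(two_choice_tasks)) {
      return(!(task %in% two_choice_tasks))
    }
    if ("n_alternatives" %in% names(d)) {
      return(any(d$n_alternatives > 2))
    }
    FALSE
  }
  empty <- tibble::tibble(
    v = NA_real_, a = NA_real_, ter = NA_real_,
    pc = NA_real_, mrt = NA_real_, vrt = NA_real_,
    n = NA_integer_, reason = NA_character_
  )
  trials |>
    dplyr::group_by(.data$person, .data$task) |>
    dplyr::group_modify(function(d, key) {
      out <- empty
      out$n <- nrow(d)
      if (refuse_task(key$task, d)) {
        out$reason <- "more_than_two_alternatives"
        return(out)
      }
      if (nrow(d) < min_n) {
        out$reason <- "too_few_trials"
        return(out)
      }
      pc <- edge_correct(sum(d$accuracy == 1), nrow(d))
      rts_s <- d$rt_ms[d$accuracy == 1] / 1000
      if (length(rts_s) < 2 || var(rts_s) <= 0) {
        out$reason <- "degenerate_rt_variance"
        return(out)
      }
      if (pc == 0.5) {
        out$reason <- "pc_at_chance"
        return(out)
      }
      fit <- ez_inverse(pc, mean(rts_s), var(rts_s), s = s)
      tibble::tibble(
        v = fit$v, a = fit$a, ter = fit$ter,
        pc = pc, mrt = mean(rts_s), vrt = var(rts_s),
        n = nrow(d), reason = NA_character_
      )
    }) |>
    dplyr::ungroup()
}
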