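# ggplot2 displays for the package's result types.

#' Plot an attentional-blink report function
#'
#' Median T2|T1 report proportion by lag with a bootstrapped confidence
#' band, one panel per task.
#'
#' @param ci Output of [ab_curve_ci()].
#' @return A ggplot object.
#' @export
plot_ab_curve <- function(ci) {
  check_columns(ci, c("task", "lag", "median_p", "lower", "upper"), "ci")
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$lag, y = .data$median_p)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::scale_x_continuous(breaks = 1:8) +
    ggplot2::labs(
      x = "T2 lag (x 100 ms after T1)",
      y = "median P(T2 correct | T1 correct)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot RT-band correlation trajectories
#'
#' One line per task: the correlation of each RT band's median with the
#' criterion, with its confidence interval. A rising |r| toward the slow
#' bands is the worst-performance-rule signature.
#'
#' @param trajectory Output of [band_trajectory()].
#' @return A ggplot object.
#' @export
plot_band_trajectory <- function(trajectory) {
  check_columns(
    trajectory, c("task", "band", "r", "ci_lower", "ci_upper"), "trajectory"
  )
  ggplot2::ggplot(trajectory, ggplot2::aes(x = .data$band, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(
      x = "RT band (1 = fastest 5%)",
      y = "r with criterion composite"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ex-Gaussian fit against the empirical distribution
#'
#' Histogram of the response times with the fitted ex-Gaussian density
#' overlaid.
#'
#' @param rts Response times (ms).
#' @param fit An `exgauss_fit` object.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_exgauss_fit <- function(rts, fit, bins = 40) {
  stopifnot(inherits(fit, "exgauss_fit"))
  df <- tibble::tibble(rt = rts)
  grid <- tibble::tibble(
    rt = seq(min(rts), max(rts), length.out = 400)
  )
  grid$density <- dexgauss(grid$rt, fit$mu, fit$sigma, fit$tau)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rt)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, fill = "grey80", colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$density),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(x = "RT (ms)", y = "density") +
    ggplot2::theme_minimal()
}
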