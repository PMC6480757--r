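# Package-wide conventions shared by every module.

#' Package-wide quantile convention
#'
#' All quantiles in the package (screening fences, score quantiles, RT bands,
#' medians) use linear interpolation between order statistics
#' (`stats::quantile(type = 7)`), stated here once so that every module is
#' consistent.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, unnamed.
#' @export
ms_quantile <- function(x, probs) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE))
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations (must exceed 3).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(is.finite(r), abs(r) <= 1, n > 3)
  if (abs(r) == 1) {
    return(c(lower = r, upper = r))
  }
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - crit * se), upper = tanh(z + crit * se))
}

# Deterministic per-unit substream seed derived from a master seed so that a
# subset of persons/tasks can be regenerated without replaying the whole run.
# Polynomial rolling hash over the key characters/digits (position-sensitive,
# exact in doubles since h * 131 + c stays far below 2^53), folded into the
# 31-bit range R accepts.
substream_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (k in list(...)) {
    codes <- if (is.character(k)) {
      utf8ToInt(paste(k, collapse = "/"))
    } else {
      as.numeric(k)
    }
    for (cc in codes) {
      h <- (h * 131 + cc + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Internal: check a data frame has the named columns.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
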