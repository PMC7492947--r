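#' Per-arm summary statistic for one continuous endpoint
#'
#' @param mean,sd,n arithmetic mean, standard deviation (>= 0) and
#'   sample size (>= 2) of one arm.
#' @return An object of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n) {
  check_that(is.finite(mean), "mean", "must be finite")
  check_that(is.finite(sd) && sd >= 0, "sd", "must be >= 0")
  check_that(n >= 2 && n == round(n), "n", "must be an integer >= 2")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stat")
}

as_summary <- function(x, what) {
  if (inherits(x, "summary_stat")) return(x)
  check_that(is.numeric(x) && length(x) >= 2, what,
             "must be a numeric vector of observations or a summary_stat")
  summary_stat(mean(x), stats::sd(x), length(x))
}

#' Two-sample t-test from raw values or summary statistics
#'
#' Welch's unequal-variance form by default; the classical pooled form
#' is selectable.  Because patient-level trial data are often
#' unavailable, each arm may be given either as a numeric vector of
#' observations or as a [summary_stat()] (mean, SD, n); note that
#' p-values recomputed from rounded printed summaries can differ from
#' the originals in the third decimal.
#'
#' If both arms have zero variance, equal means give `t = 0`, `p = 1`
#' by convention (a message is emitted) and unequal means give `p = 0`.
#'
#' @param x,y numeric vectors or [summary_stat()] objects, one per arm.
#' @param var_equal use the pooled-variance form.
#' @return List with `t`, `df`, `p_value`, `method`, and the mean
#'   difference `estimate` (x minus y).
#' @examples
#' two_sample_t(summary_stat(62.9, 13.7, 105),
#'              summary_stat(61.2, 10.9, 106))   # t = 0.997, p = 0.320
#' @export
two_sample_t <- function(x, y, var_equal = FALSE) {
  sx <- as_summary(x, "x"); sy <- as_summary(y, "y")
  diff <- sx$mean - sy$mean
  if (var_equal) {
    df <- sx$n + sy$n - 2
    sp2 <- ((sx$n - 1) * sx$sd^2 + (sy$n - 1) * sy$sd^2) / df
    se <- sqrt(sp2 * (1 / sx$n + 1 / sy$n))
    method <- "pooled"
  } else {
    v1 <- sx$sd^2 / sx$n; v2 <- sy$sd^2 / sy$n
    se <- sqrt(v1 + v2)
    df <- if (se > 0) {
      (v1 + v2)^2 / (v1^2 / (sx$n - 1) + v2^2 / (sy$n - 1))
    } else NA_real_
    method <- "welch"
  }
  if (se == 0) {
    if (diff == 0) {
      message("both arms have zero variance and equal means; p = 1 by convention")
      return(list(t = 0, df = df, p_value = 1, method = method,
                  estimate = diff))
    }
    return(list(t = sign(diff) * Inf, df = df, p_value = 0,
                method = method, estimate = diff))
  }
  tval <- diff / se
  list(t = tval, df = df, p_value = 2 * pt(-abs(tval), df),
       method = method, estimate = diff)
}
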