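#' Trapezoidal area under an enzyme-release curve
#'
#' Composite trapezoid rule over the sampled points, clipped to a time
#' window.  Where samples straddle a window edge the curve is
#' interpolated linearly to the edge; the integral is never extrapolated
#' beyond the observed time range.  Used as the infarct-size surrogate
#' on CK-MB release curves over 0-72 h.
#'
#' @param time sampling times (h), strictly increasing, at least two.
#' @param value sampled concentrations (U/L), same length as `time`.
#' @param window integration window `c(lo, hi)` in hours; default
#'   `c(0, 72)`.
#' @return The area (U·h/L).
#' @examples
#' auc_trapezoid(c(0, 6, 12), c(0, 10, 0))   # 60
#' @export
auc_trapezoid <- function(time, value, window = c(0, 72)) {
  check_that(is.numeric(time) && is.numeric(value) &&
               length(time) == length(value) && length(time) >= 2,
             "series", "need at least two (time, value) points")
  check_that(all(diff(time) > 0), "time", "times must be strictly increasing")
  check_that(length(window) == 2 && window[1] < window[2], "window",
             "must be c(lo, hi) with lo < hi")
  lo <- max(window[1], min(time)); hi <- min(window[2], max(time))
  if (lo >= hi) return(0)
  inside <- time > lo & time < hi
  tt <- c(lo, time[inside], hi)
  vv <- c(stats::approx(time, value, xout = lo)$y, value[inside],
          stats::approx(time, value, xout = hi)$y)
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
}
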