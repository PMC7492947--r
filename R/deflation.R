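# Parametric balloon radius-time deflation profiles.
#
# The measured bench quantity being emulated is the characteristic radial
# collapse speed of the balloon surface (vb, mm/s).  The profile is a
# quarter-sine: collapse is fastest the instant pressure is released and
# decays smoothly to zero as the balloon empties, so the peak speed
# equals multiplier * vb exactly and occurs while the annular gap is
# still thin.

#' Balloon deflation protocol
#'
#' @param mode `"rapid"` (abrupt collapse over `rapid_duration`) or
#'   `"slow"` (pressure bled at `slow_rate`, paced through a linear
#'   pressure-to-radius map so the deflation lasts
#'   `start_pressure / slow_rate` seconds).
#' @param start_pressure inflation pressure at release (atm).
#' @param slow_rate pressure bleed rate for slow mode (atm/s; clinical
#'   protocol: 2).
#' @param rapid_duration collapse duration for rapid mode (s).
#' @return An object of class `deflation_protocol`.
#' @export
deflation_protocol <- function(mode = c("rapid", "slow"),
                               start_pressure = 16, slow_rate = 2,
                               rapid_duration = 1.5) {
  mode <- match.arg(mode)
  check_that(start_pressure > 0, "start_pressure", "must be > 0")
  check_that(slow_rate > 0, "slow_rate", "must be > 0")
  check_that(rapid_duration > 0, "rapid_duration", "must be > 0")
  structure(list(mode = mode, start_pressure = start_pressure,
                 slow_rate = slow_rate, rapid_duration = rapid_duration),
            class = "deflation_protocol")
}

#' Generate a balloon deflation profile
#'
#' Builds a smooth (C1 on the deflation interval) monotone
#' non-increasing balloon radius-time curve from `Rb0` down to `Rb_min`
#' whose peak collapse speed is exactly `multiplier * vb`.  The shape is
#' a quarter-sine, so the total deflation time is
#' \eqn{T = \pi (R_{b0} - R_{b,min}) / (2\, m\, v_b)} and doubling the
#' multiplier halves the duration.  Outside `[0, T]` the radius is
#' clamped to its endpoint values.
#'
#' When a [deflation_protocol()] is supplied and `vb` is `NULL`, the
#' reference speed is derived from the protocol: rapid mode compresses
#' the full radius excursion into `rapid_duration`; slow mode paces it
#' by the pressure bleed time `start_pressure / slow_rate` through a
#' linear pressure-to-radius map.
#'
#' An axial taper models the balloon shoulders: the local radius is
#' `taper(x/L) * Rb(t)` with `taper` rising from `shoulder_floor` at the
#' balloon ends to 1 over a fraction `shoulder_frac` of the length.
#'
#' @param protocol optional [deflation_protocol()].
#' @param geometry optional [vessel_geometry()]; used to default `Rb0`
#'   to a 50 micron initial gap and to reject balloons wider than the
#'   lumen.
#' @param vb reference radial collapse speed (mm/s); default 1.5 when no
#'   protocol is given.
#' @param multiplier deflation-velocity scenario factor (0.5, 1 or 2 in
#'   the comparisons; any positive value is accepted).
#' @param Rb0 initial balloon outer radius (mm).
#' @param Rb_min final (folded) balloon radius (mm); kept above zero so
#'   the annular solver stays non-singular.
#' @param shoulder_frac,shoulder_floor axial taper parameters.
#' @return An object of class `deflation_profile` with fields `radius(t)`
#'   and `speed(t)` (vectorized, seconds in / mm out), `taper(xfrac)`,
#'   `T_deflate`, `vb`, `multiplier`, `Rb0`, `Rb_min`.
#' @examples
#' prof <- generate_deflation_profile(vb = 1.5, multiplier = 1, Rb0 = 1.45)
#' prof$T_deflate
#' max(abs(prof$speed(seq(0, prof$T_deflate, by = 1e-3))))  # = 1.5 mm/s
#' @export
generate_deflation_profile <- function(protocol = NULL, geometry = NULL,
                                       vb = NULL, multiplier = 1,
                                       Rb0 = NULL, Rb_min = 0.05,
                                       shoulder_frac = 0.05,
                                       shoulder_floor = 0.5) {
  check_that(multiplier > 0, "multiplier", "must be > 0")
  if (!is.null(geometry)) {
    if (is.null(Rb0)) Rb0 <- geometry$R_v - 0.05
    if (Rb0 >= geometry$R_v) {
      stop("geometry error: balloon radius Rb0 (", Rb0,
           " mm) must be smaller than the vessel radius R_v (",
           geometry$R_v, " mm)", call. = FALSE)
    }
  }
  check_that(!is.null(Rb0) && Rb0 > Rb_min, "Rb0",
             "must be given (or derivable from geometry) and exceed Rb_min")
  check_that(Rb_min > 0, "Rb_min", "must be > 0")
  dR <- Rb0 - Rb_min
  if (is.null(vb)) {
    if (is.null(protocol)) {
      vb <- 1.5
    } else {
      T_base <- switch(protocol$mode,
                       rapid = protocol$rapid_duration,
                       slow = protocol$start_pressure / protocol$slow_rate)
      vb <- pi * dR / (2 * T_base)
    }
  }
  check_that(vb > 0, "vb", "must be > 0")
  v_peak <- multiplier * vb
  T_def <- pi * dR / (2 * v_peak)
  radius <- function(t) {
    u <- pmin(pmax(t / T_def, 0), 1)
    Rb0 - dR * sin(pi * u / 2)
  }
  speed <- function(t) {
    ifelse(t < 0 | t > T_def, 0,
           -v_peak * cos(pi * t / (2 * T_def)))
  }
  sf <- shoulder_frac
  taper <- function(xfrac) {
    xf <- pmin(pmax(xfrac, 0), 1)
    edge <- pmin(xf, 1 - xf)
    ifelse(edge >= sf | sf <= 0, 1,
           shoulder_floor + (1 - shoulder_floor) * sin(pi * edge / (2 * sf)))
  }
  structure(list(vb = vb, multiplier = multiplier, Rb0 = Rb0,
                 Rb_min = Rb_min, T_deflate = T_def, radius = radius,
                 speed = speed, taper = taper,
                 shoulder_frac = shoulder_frac,
                 shoulder_floor = shoulder_floor,
                 protocol = protocol),
            class = "deflation_profile")
}

#' @export
print.deflation_profile <- function(x, ...) {
  cat(sprintf(paste0("<deflation_profile> %.2f -> %.2f mm over %.3f s ",
                     "(vb = %.3g mm/s, multiplier %.2g)\n"),
              x$Rb0, x$Rb_min, x$T_deflate, x$vb, x$multiplier))
  invisible(x)
}
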