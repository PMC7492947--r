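# Quasi-one-dimensional lubrication model of the balloon-vessel gap.
#
# During deflation the annular gap between balloon and wall widens;
# with inertia neglected in the thin gap (validity guarded by the
# reduced Reynolds number), the flow at each instant is an annular
# Poiseuille network driven by the perfusion pressures plus the volume
# flux absorbed by the moving wall.  Axial mass conservation,
#   dQ/dx = -dA_gap/dt,
# makes Q piecewise linear on the grid; the single free constant (the
# inlet flow) follows from the series pressure-drop equation
#   P_in - P_out = sum_i R_i Q_i + R_distal Q_out.
# All internal computation is SI; configuration and reported states use
# clinical units (mm, mmHg, mL/s).

#' Vessel geometry for the gap-flow model
#'
#' @param R_v vessel lumen radius (mm).
#' @param L_prox,L_bal,L_dist proximal, balloon and distal segment
#'   lengths (mm).
#' @param n_x number of axial grid cells over the balloon (>= 16).
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(R_v = 1.5, L_prox = 20, L_bal = 20,
                            L_dist = 20, n_x = 64) {
  check_that(R_v > 0, "R_v", "must be > 0")
  for (nm in c("L_prox", "L_bal", "L_dist")) {
    check_that(get(nm) > 0, nm, "must be > 0")
  }
  check_that(n_x >= 16 && n_x == round(n_x), "n_x",
             "must be an integer >= 16")
  structure(list(R_v = R_v, L_prox = L_prox, L_bal = L_bal,
                 L_dist = L_dist, n_x = as.integer(n_x)),
            class = "vessel_geometry")
}

#' Fluid properties
#'
#' Presets: `"blood-analog"` (mu = 3.5 mPa s, rho = 1060 kg/m3) for
#' physiological interpretation, `"water"` (mu = 1.0 mPa s, rho = 1000)
#' mirroring a dyed-water bench rig.
#'
#' @param preset `"blood-analog"` or `"water"`.
#' @param mu,rho optional overrides: dynamic viscosity (Pa s) and
#'   density (kg/m3).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(preset = c("blood-analog", "water"),
                             mu = NULL, rho = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
                "blood-analog" = list(mu = 3.5e-3, rho = 1060),
                "water" = list(mu = 1.0e-3, rho = 1000))
  if (is.null(mu)) mu <- def$mu
  if (is.null(rho)) rho <- def$rho
  check_that(mu > 0, "mu", "must be > 0")
  check_that(rho > 0, "rho", "must be > 0")
  structure(list(preset = preset, mu = mu, rho = rho),
            class = "fluid_properties")
}

#' Hydraulic resistance per unit length of a concentric annulus
#'
#' Poiseuille flow between a fixed outer wall of radius `R_v` and an
#' inner boundary of radius `R_b`:
#' \deqn{R' = 8\mu / \big(\pi [R_v^4 - R_b^4 - (R_v^2-R_b^2)^2/\ln(R_v/R_b)]\big).}
#' Reduces to the open-tube value \eqn{8\mu/(\pi R_v^4)} as
#' \eqn{R_b \to 0} and to the plane-channel lubrication value in the
#' thin-gap limit; strictly increasing as the gap closes.
#'
#' @param R_v outer (vessel) radius (m).
#' @param R_b inner (balloon) radius (m), in `[0, R_v)`; vectorized.
#' @param mu dynamic viscosity (Pa s).
#' @return Resistance per unit length (Pa s / m4).
#' @export
annulus_resistance <- function(R_v, R_b, mu) {
  check_that(R_v > 0 && mu > 0, "R_v/mu", "must be > 0")
  if (any(R_b >= R_v)) {
    stop("geometry error: balloon radius R_b must be smaller than the ",
         "vessel radius R_v", call. = FALSE)
  }
  check_that(all(R_b >= 0), "R_b", "must be >= 0")
  geom <- ifelse(R_b == 0, R_v^4,
                 R_v^4 - R_b^4 - (R_v^2 - R_b^2)^2 / log(R_v / R_b))
  8 * mu / (pi * geom)
}

#' Wall shear stress on the vessel wall of a concentric annulus
#'
#' Evaluates \eqn{\mu |du/dr|} at `r = R_v` for the annular Poiseuille
#' profile carrying volumetric flow `Q`.  With `R_b = 0` this is the
#' open-tube value \eqn{4\mu|Q|/(\pi R_v^3)}.
#'
#' @param Q volumetric flow (m3/s, sign ignored); vectorized with `R_b`.
#' @inheritParams annulus_resistance
#' @return Wall shear stress magnitude (Pa).
#' @export
annulus_wall_shear <- function(Q, R_v, R_b, mu) {
  n <- max(length(Q), length(R_b))
  Q <- rep_len(Q, n); R_b <- rep_len(R_b, n)
  G <- abs(Q) * annulus_resistance(R_v, R_b, mu)  # pressure gradient
  shape <- ifelse(R_b == 0, 2 * R_v,
                  abs(2 * R_v - (R_v^2 - R_b^2) / (R_v * log(R_v / R_b))))
  G * shape / 4
}

#' Gap-flow simulation configuration
#'
#' @param geometry a [vessel_geometry()].
#' @param fluid a [fluid_properties()].
#' @param profile a [generate_deflation_profile()] result; defaults to
#'   the baseline profile for this geometry.
#' @param P_in,P_out inlet and outlet perfusion pressures (mmHg);
#'   `P_in >= P_out` (equality gives a purely suction-driven flow).
#' @param distal_resistance lumped resistance terminating the outlet
#'   (mmHg s/mL).
#' @param dt time step (s).
#' @param gap_floor minimum admissible annular gap (mm); the balloon
#'   radius is clamped below `R_v - gap_floor` and clamping is recorded
#'   on the returned states.
#' @param settle extra simulated time after full deflation (s).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(geometry = vessel_geometry(),
                              fluid = fluid_properties(),
                              profile = generate_deflation_profile(
                                geometry = geometry),
                              P_in = 120, P_out = 20,
                              distal_resistance = 75,
                              dt = 1e-3, gap_floor = 0.01, settle = 0.1) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(profile, "deflation_profile"))
  check_that(P_in >= P_out, "P_in", "must be at least P_out")
  check_that(distal_resistance >= 0, "distal_resistance", "must be >= 0")
  check_that(dt > 0, "dt", "must be > 0")
  check_that(gap_floor > 0, "gap_floor", "must be > 0")
  check_that(settle >= 0, "settle", "must be >= 0")
  check_that(profile$Rb0 < geometry$R_v, "profile$Rb0",
             "balloon must fit inside the vessel lumen")
  structure(list(geometry = geometry, fluid = fluid, profile = profile,
                 P_in = P_in, P_out = P_out,
                 distal_resistance = distal_resistance, dt = dt,
                 gap_floor = gap_floor, settle = settle),
            class = "sim_config")
}

#' Default simulation configuration from the shipped `sim.cfg`
#'
#' @param multiplier deflation-velocity scenario factor.
#' @param path alternative configuration file.
#' @param fluid_preset override of the configured fluid preset.
#' @return A [simulation_config()].
#' @export
default_sim_config <- function(multiplier = 1,
                               path = default_config_paths()[["sim"]],
                               fluid_preset = NULL) {
  cfg <- read_config(path)
  g <- cfg$geometry
  geometry <- vessel_geometry(R_v = g$R_v_mm, L_prox = g$L_prox_mm,
                              L_bal = g$L_bal_mm, L_dist = g$L_dist_mm,
                              n_x = g$n_x)
  fluid <- fluid_properties(if (is.null(fluid_preset)) cfg$fluid$preset
                            else fluid_preset)
  pr <- cfg$profile
  profile <- generate_deflation_profile(
    geometry = geometry, vb = pr$vb_mm_s, multiplier = multiplier,
    Rb0 = geometry$R_v - pr$initial_gap_mm, Rb_min = pr$Rb_min_mm,
    shoulder_frac = pr$shoulder_frac, shoulder_floor = pr$shoulder_floor)
  simulation_config(geometry = geometry, fluid = fluid, profile = profile,
                    P_in = cfg$boundary$P_in_mmHg,
                    P_out = cfg$boundary$P_out_mmHg,
                    distal_resistance = cfg$boundary$distal_resistance,
                    dt = cfg$numerics$dt_s,
                    gap_floor = cfg$numerics$gap_floor_mm,
                    settle = cfg$numerics$settle_s)
}

# SI working quantities shared by the solver
sim_internals <- function(config) {
  g <- config$geometry
  R_v <- g$R_v * 1e-3
  L_bal <- g$L_bal * 1e-3
  dx <- L_bal / g$n_x
  xm <- (seq_len(g$n_x) - 0.5) * dx
  tube_res <- 8 * config$fluid$mu / (pi * R_v^4)
  list(R_v = R_v, L_bal = L_bal, dx = dx, xm = xm,
       taper = config$profile$taper(xm / L_bal),
       R_prox = tube_res * g$L_prox * 1e-3,
       R_dist_tube = tube_res * g$L_dist * 1e-3,
       R_lump = config$distal_resistance * MMHG_PA / 1e-6,
       P_in = config$P_in * MMHG_PA, P_out = config$P_out * MMHG_PA,
       Rb_cap = R_v - config$gap_floor * 1e-3)
}

# clamped local balloon radius (m) and wall speed (m/s) at time t
balloon_state <- function(config, t, int = sim_internals(config)) {
  Rb_raw <- int$taper * config$profile$radius(t) * 1e-3
  clamped <- Rb_raw > int$Rb_cap
  Rb <- pmin(Rb_raw, int$Rb_cap)
  dRb <- int$taper * config$profile$speed(t) * 1e-3
  dRb[clamped] <- 0
  list(Rb = Rb, dRb = dRb, clamped = clamped)
}

#' Total annular gap volume at time t
#'
#' @param config a [simulation_config()].
#' @param t time (s); vectorized.
#' @return Gap volume (m3) between balloon and wall over the balloon
#'   segment, with the gap-floor clamp applied.
#' @export
gap_volume <- function(config, t) {
  int <- sim_internals(config)
  vapply(t, function(ti) {
    b <- balloon_state(config, ti, int)
    sum(pi * (int$R_v^2 - b$Rb^2) * int$dx)
  }, numeric(1))
}

#' Solve the instantaneous gap flow at one time
#'
#' Quasi-steady annular lubrication solve with the prescribed wall
#' motion at time `t`: the axial flow profile, pressures, mean gap
#' velocities and wall shear stresses over the balloon, plus the
#' downstream wall shear stress.
#'
#' @inheritParams gap_volume
#' @param t time (s), scalar.
#' @return An object of class `gap_flow_state`: `t`; node positions
#'   `x_mm` and flows `Q_mL_s` (piecewise-linear, positive toward the
#'   outlet); cell-centre `p_mmHg`, `u_gap_m_s`, `tau_w_Pa`, `gap_mm`;
#'   scalars `Q_in_mL_s`, `Q_out_mL_s`, `tau_downstream_Pa`,
#'   `p_outlet_mmHg`, `mass_residual`, `clamped`.
#' @export
solve_gap_flow <- function(config, t) {
  stopifnot(inherits(config, "sim_config"), length(t) == 1, is.finite(t))
  int <- sim_internals(config)
  b <- balloon_state(config, t, int)
  mu <- config$fluid$mu
  # wall-motion source: dQ/dx = -dA_gap/dt
  src <- -2 * pi * b$Rb * b$dRb            # >= 0 during deflation
  S <- cumsum(src * int$dx)
  Stot <- S[length(S)]
  Sm <- (c(0, S[-length(S)]) + S) / 2
  Rcell <- annulus_resistance(int$R_v, b$Rb, mu) * int$dx
  a_tot <- int$R_prox + sum(Rcell) + int$R_dist_tube + int$R_lump
  b_tot <- sum(Rcell * Sm) + (int$R_dist_tube + int$R_lump) * Stot
  Q_in <- (int$P_in - int$P_out + b_tot) / a_tot
  Q_bar <- Q_in - Sm
  Q_out <- Q_in - Stot
  Q_nodes <- c(Q_in, Q_in - S)
  p_bal_in <- int$P_in - int$R_prox * Q_in
  p_mid <- p_bal_in - (cumsum(Rcell * Q_bar) - Rcell * Q_bar / 2)
  p_out_node <- p_bal_in - sum(Rcell * Q_bar) - int$R_dist_tube * Q_out
  A_gap <- pi * (int$R_v^2 - b$Rb^2)
  if (!all(is.finite(c(Q_in, Q_bar, p_mid)))) {
    stop("non-finite gap-flow solve at t = ", t, "; config: R_v = ",
         config$geometry$R_v, " mm, multiplier = ",
         config$profile$multiplier, call. = FALSE)
  }
  dVdt <- Stot
  resid <- abs(Q_in - Q_out - dVdt) /
    max(abs(Q_in), abs(dVdt), .Machine$double.eps)
  structure(list(
    t = t,
    x_mm = seq(0, int$L_bal, by = int$dx) * 1e3,
    Q_mL_s = Q_nodes * 1e6,
    x_mid_mm = int$xm * 1e3,
    p_mmHg = p_mid / MMHG_PA,
    u_gap_m_s = Q_bar / A_gap,
    tau_w_Pa = annulus_wall_shear(Q_bar, int$R_v, b$Rb, mu),
    gap_mm = (int$R_v - b$Rb) * 1e3,
    Q_in_mL_s = Q_in * 1e6, Q_out_mL_s = Q_out * 1e6,
    tau_downstream_Pa = 4 * mu * abs(Q_out) / (pi * int$R_v^3),
    p_outlet_mmHg = p_out_node / MMHG_PA,
    mass_residual = resid,
    clamped = any(b$clamped)),
    class = "gap_flow_state")
}

#' Reduced Reynolds number of a gap-flow state
#'
#' Validity guard for the quasi-steady lubrication assumption:
#' \eqn{Re^* = (\rho u h / \mu)(h / L_{bal})} evaluated at the cell of
#' peak gap speed; above 1 the neglected inertia is no longer small and
#' a warning flag is set.
#'
#' @param state a [solve_gap_flow()] result.
#' @param fluid a [fluid_properties()].
#' @param geometry a [vessel_geometry()].
#' @return List with `re_star` and logical `warning`.
#' @export
reynolds_check <- function(state, fluid, geometry) {
  stopifnot(inherits(state, "gap_flow_state"))
  i <- which.max(abs(state$u_gap_m_s))
  u <- abs(state$u_gap_m_s[i])
  h <- state$gap_mm[i] * 1e-3
  re <- (fluid$rho * u * h / fluid$mu) * (h / (geometry$L_bal * 1e-3))
  list(re_star = re, warning = re > 1)
}

#' Run a transient deflation simulation
#'
#' Time-steps [solve_gap_flow()] over the deflation and a settling
#' interval, recording per step the spatial peak wall shear stress
#' under the balloon, the peak mean gap speed, and the downstream wall
#' shear stress.  The physiological reference is the downstream wall
#' shear stress of the fully-deflated steady state.  Deterministic: no
#' randomness enters.
#'
#' @param config a [simulation_config()].
#' @return An object of class `gap_sim_result`: a `series` tibble
#'   (`time`, `peak_tau_balloon`, `peak_u_gap`, `tau_downstream`),
#'   scalars `tau_physiological`, `peak_tau_max`, `peak_u_max`,
#'   `wss_ratio` (= `peak_tau_max / tau_physiological`),
#'   `max_mass_residual`, `re_star_max` / `re_star_at_peak` /
#'   `re_warning` (lubrication validity guard), `multiplier`, and the
#'   `config`.
#' @examples
#' \donttest{
#' res <- run_simulation(default_sim_config(multiplier = 1))
#' res$wss_ratio   # > 60
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  times <- seq(0, config$profile$T_deflate + config$settle, by = config$dt)
  n <- length(times)
  peak_tau <- peak_u <- tau_down <- resid <- re_star <- numeric(n)
  clamped_any <- FALSE
  for (i in seq_len(n)) {
    st <- solve_gap_flow(config, times[i])
    peak_tau[i] <- max(st$tau_w_Pa)
    peak_u[i] <- max(abs(st$u_gap_m_s))
    tau_down[i] <- st$tau_downstream_Pa
    resid[i] <- st$mass_residual
    re_star[i] <- reynolds_check(st, config$fluid, config$geometry)$re_star
    clamped_any <- clamped_any || st$clamped
  }
  steady <- solve_gap_flow(config,
                           config$profile$T_deflate + config$settle + 1)
  tau_phys <- steady$tau_downstream_Pa
  structure(list(
    series = tibble(time = times, peak_tau_balloon = peak_tau,
                    peak_u_gap = peak_u, tau_downstream = tau_down),
    tau_physiological = tau_phys,
    peak_tau_max = max(peak_tau), peak_u_max = max(peak_u),
    wss_ratio = max(peak_tau) / tau_phys,
    max_mass_residual = max(resid),
    re_star_max = max(re_star), re_warning = max(re_star) > 1,
    re_star_at_peak = re_star[which.max(peak_tau)],
    clamped = clamped_any,
    multiplier = config$profile$multiplier,
    config = config),
    class = "gap_sim_result")
}

#' @export
print.gap_sim_result <- function(x, ...) {
  cat(sprintf(paste0("<gap_sim_result> multiplier %.2g: peak WSS %.1f Pa, ",
                     "peak gap speed %.3f m/s,\n  physiological WSS %.2f Pa ",
                     "(ratio %.1f)\n"),
              x$multiplier, x$peak_tau_max, x$peak_u_max,
              x$tau_physiological, x$wss_ratio))
  invisible(x)
}

#' Compare deflation-velocity scenarios
#'
#' Aligns several [run_simulation()] results (same geometry, fluid and
#' boundary conditions; different deflation-velocity multipliers) into
#' a scalar summary and a long time-series table.
#'
#' @param results list of `gap_sim_result` objects (>= 2).
#' @return An object of class `gap_scenarios`: `summary` tibble
#'   (`multiplier`, `T_deflate`, `peak_wss_Pa`, `peak_gap_velocity_m_s`,
#'   `tau_physiological_Pa`, `wss_ratio`) and `series` long tibble.
#' @export
scenario_report <- function(results) {
  stopifnot(is.list(results), length(results) >= 2,
            all(vapply(results, inherits, logical(1), "gap_sim_result")))
  key <- function(r) {
    c(unlist(r$config$geometry), mu = r$config$fluid$mu,
      rho = r$config$fluid$rho, P_in = r$config$P_in,
      P_out = r$config$P_out, Rd = r$config$distal_resistance)
  }
  k0 <- key(results[[1]])
  for (r in results[-1]) {
    if (!isTRUE(all.equal(key(r), k0))) {
      stop("scenario results use mismatched geometry/fluid/boundary ",
           "conditions", call. = FALSE)
    }
  }
  summary <- do.call(rbind, lapply(results, function(r) {
    tibble(multiplier = r$multiplier,
           T_deflate = r$config$profile$T_deflate,
           peak_wss_Pa = r$peak_tau_max,
           peak_gap_velocity_m_s = r$peak_u_max,
           tau_physiological_Pa = r$tau_physiological,
           wss_ratio = r$wss_ratio)
  }))
  series <- do.call(rbind, lapply(results, function(r) {
    cbind(tibble(multiplier = rep(r$multiplier, nrow(r$series))), r$series)
  }))
  structure(list(summary = summary, series = as_tibble(series)),
            class = "gap_scenarios")
}

#' @export
print.gap_scenarios <- function(x, ...) {
  cat("<gap_scenarios>\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.gap_scenarios <- function(x, which = c("wss", "velocity"), ...) {
  which <- match.arg(which)
  col <- if (which == "wss") "peak_tau_balloon" else "peak_u_gap"
  mults <- sort(unique(x$series$multiplier))
  cols <- seq_along(mults)
  plot(NULL, xlim = range(x$series$time), ylim = range(x$series[[col]]),
       xlab = "time (s)",
       ylab = if (which == "wss") "peak balloon-area WSS (Pa)"
              else "peak gap velocity (m/s)", ...)
  for (i in seq_along(mults)) {
    s <- x$series[x$series$multiplier == mults[i], ]
    lines(s$time, s[[col]], col = cols[i])
  }
  legend("topright", legend = sprintf("%.1f vb", mults), col = cols,
         lty = 1, bty = "n")
  invisible(x)
}
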