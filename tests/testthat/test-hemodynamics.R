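mu_b <- 3.5e-3
R_v <- 1.5e-3

test_that("annulus resistance recovers its Poiseuille and lubrication limits", {
  open <- 8 * mu_b / (pi * R_v^4)
  # vanishing inner boundary: exactly open-tube Poiseuille at R_b = 0;
  # for small R_b > 0 the approach is logarithmic (a thin central wire
  # still adds ~1/log drag), so the correct asymptotic check is that
  # the leading 1/log correction accounts for the gap to 0.1%
  expect_equal(annulus_resistance(R_v, 0, mu_b), open)
  Rb_small <- R_v * 1e-4
  corr <- 1 - 1 / log(R_v / Rb_small)
  expect_equal(annulus_resistance(R_v, Rb_small, mu_b) * corr, open,
               tolerance = 1e-3)
  # and the approach to the open-tube value is monotone
  expect_lt(abs(annulus_resistance(R_v, R_v * 1e-8, mu_b) - open),
            abs(annulus_resistance(R_v, R_v * 1e-4, mu_b) - open))
  # thin gap: plane channel 12 mu / (w h^3), w = 2 pi R_mean, within 2%
  h <- 0.01 * R_v
  Rb <- R_v - h
  plane <- 12 * mu_b / (2 * pi * (R_v + Rb) / 2 * h^3)
  expect_equal(annulus_resistance(R_v, Rb, mu_b), plane, tolerance = 0.02)
  # strictly increasing as the gap closes
  expect_gt(annulus_resistance(R_v, 0.9 * R_v, mu_b),
            annulus_resistance(R_v, 0.5 * R_v, mu_b))
  expect_error(annulus_resistance(R_v, R_v, mu_b), "geometry")
})

test_that("annular wall shear matches the open-tube closed form and is linear in Q", {
  Q <- 1e-6  # 1 mL/s
  expect_equal(annulus_wall_shear(Q, R_v, 0, mu_b),
               4 * mu_b * Q / (pi * R_v^3))
  expect_equal(round(annulus_wall_shear(Q, R_v, 0, mu_b), 2), 1.32)
  expect_equal(annulus_wall_shear(0, R_v, 0.5 * R_v, mu_b), 0)
  expect_equal(annulus_wall_shear(2 * Q, R_v, 0.7 * R_v, mu_b),
               2 * annulus_wall_shear(Q, R_v, 0.7 * R_v, mu_b))
})

test_that("wall shear agrees with numerical differentiation of the velocity profile", {
  set.seed(17)
  for (i in 1:50) {
    Rb <- runif(1, 0.05, 0.97) * R_v
    Q <- runif(1, 0.01, 5) * 1e-6
    G <- Q * annulus_resistance(R_v, Rb, mu_b)   # pressure gradient
    u <- function(r) {
      (G / (4 * mu_b)) *
        (R_v^2 - r^2 - (R_v^2 - Rb^2) * log(R_v / r) / log(R_v / Rb))
    }
    # the profile must integrate back to Q (quadrature oracle) ...
    Q_num <- integrate(function(r) 2 * pi * r * u(r), Rb, R_v,
                       rel.tol = 1e-12)$value
    expect_equal(Q_num, Q, tolerance = 1e-8)
    # ... and its one-sided numerical wall gradient must match
    eps <- R_v * 1e-5
    dudr <- (3 * u(R_v) - 4 * u(R_v - eps) + u(R_v - 2 * eps)) / (2 * eps)
    expect_equal(mu_b * abs(dudr), annulus_wall_shear(Q, R_v, Rb, mu_b),
                 tolerance = 1e-8)
  }
})

test_that("a static balloon gives the uniform series-circuit flow", {
  cfg <- default_sim_config(multiplier = 1)
  st <- solve_gap_flow(cfg, -1)  # before release: static at Rb0
  expect_lt(diff(range(st$Q_mL_s)), 1e-12 * max(abs(st$Q_mL_s)))
  int_Rv <- cfg$geometry$R_v * 1e-3
  tube_res <- 8 * cfg$fluid$mu / (pi * int_Rv^4)
  Rb <- cfg$profile$taper(((1:cfg$geometry$n_x) - 0.5) / cfg$geometry$n_x) *
    cfg$profile$Rb0 * 1e-3
  dx <- cfg$geometry$L_bal * 1e-3 / cfg$geometry$n_x
  total <- tube_res * (cfg$geometry$L_prox + cfg$geometry$L_dist) * 1e-3 +
    sum(annulus_resistance(int_Rv, Rb, cfg$fluid$mu) * dx) +
    cfg$distal_resistance * 133.322 / 1e-6
  Q_expect <- (cfg$P_in - cfg$P_out) * 133.322 / total
  expect_equal(st$Q_in_mL_s, Q_expect * 1e6, tolerance = 1e-10)
})

test_that("equal perfusion pressures give symmetric suction from both ends", {
  geo <- vessel_geometry(L_prox = 20, L_dist = 20)
  cfg <- simulation_config(geometry = geo, P_in = 50, P_out = 50,
                           distal_resistance = 0)
  st <- solve_gap_flow(cfg, 0.2)
  expect_lt(abs(st$Q_in_mL_s + st$Q_out_mL_s),
            1e-10 * max(abs(st$Q_mL_s)))
})

test_that("the solver conserves mass against direct volume differentiation", {
  cfg <- default_sim_config(multiplier = 1)
  delta <- 1e-5
  for (t in c(0.05, 0.3, 0.8, 1.2)) {
    st <- solve_gap_flow(cfg, t)
    expect_lt(st$mass_residual, 1e-8)
    dVdt_num <- (gap_volume(cfg, t + delta) - gap_volume(cfg, t - delta)) /
      (2 * delta)
    flux_gap <- (st$Q_in_mL_s - st$Q_out_mL_s) * 1e-6
    expect_equal(flux_gap, dVdt_num, tolerance = 1e-9)
  }
})

test_that("reconstructed pressures satisfy both boundary conditions", {
  cfg <- default_sim_config(multiplier = 1)
  for (t in c(-1, 0.1, 0.9)) {
    st <- solve_gap_flow(cfg, t)
    expect_equal(st$p_outlet_mmHg,
                 cfg$P_out + cfg$distal_resistance * st$Q_out_mL_s,
                 tolerance = 1e-10)
    # pressure falls from the inlet across the proximal tube
    expect_lt(st$p_mmHg[1], cfg$P_in)
  }
})

test_that("reduced Reynolds number guards the lubrication assumption", {
  fake_state <- function(u, gap_mm) {
    structure(list(u_gap_m_s = u, gap_mm = gap_mm),
              class = "gap_flow_state")
  }
  water <- fluid_properties("water")
  geo <- vessel_geometry(L_bal = 20)
  # hand arithmetic: (1000 * 1 * 5e-5 / 1e-3) * (5e-5 / 0.02) = 0.125
  rc <- reynolds_check(fake_state(1, 0.05), water, geo)
  expect_equal(rc$re_star, 0.125)
  expect_false(rc$warning)
  expect_equal(reynolds_check(fake_state(0, 0.05), water, geo)$re_star, 0)
  expect_true(reynolds_check(fake_state(1, 5), water, geo)$warning)
})

sim_cache <- new.env()
get_sim <- function(m, dt_scale = 1, nx_scale = 1) {
  key <- sprintf("m%g_d%g_n%g", m, dt_scale, nx_scale)
  if (is.null(sim_cache[[key]])) {
    cfg <- default_sim_config(multiplier = m)
    if (dt_scale != 1 || nx_scale != 1) {
      geo <- cfg$geometry
      geo2 <- vessel_geometry(geo$R_v, geo$L_prox, geo$L_bal, geo$L_dist,
                              geo$n_x * nx_scale)
      cfg <- simulation_config(
        geometry = geo2, fluid = cfg$fluid,
        profile = generate_deflation_profile(
          geometry = geo2, vb = cfg$profile$vb, multiplier = m,
          Rb0 = cfg$profile$Rb0, Rb_min = cfg$profile$Rb_min,
          shoulder_frac = cfg$profile$shoulder_frac,
          shoulder_floor = cfg$profile$shoulder_floor),
        P_in = cfg$P_in, P_out = cfg$P_out,
        distal_resistance = cfg$distal_resistance,
        dt = cfg$dt * dt_scale, gap_floor = cfg$gap_floor,
        settle = cfg$settle)
    }
    sim_cache[[key]] <- run_simulation(cfg)
  }
  sim_cache[[key]]
}

test_that("peak gap velocity and wall shear rise strictly with deflation speed", {
  r05 <- get_sim(0.5); r1 <- get_sim(1); r2 <- get_sim(2)
  expect_lt(r05$peak_u_max, r1$peak_u_max)
  expect_lt(r1$peak_u_max, r2$peak_u_max)
  expect_lt(r05$peak_tau_max, r1$peak_tau_max)
  expect_lt(r1$peak_tau_max, r2$peak_tau_max)
  expect_lt(max(r1$series$peak_tau_balloon), Inf)
  # every step conserved mass
  expect_lt(r1$max_mass_residual, 1e-8)
})

test_that("the deflation transient dwarfs the physiological wall shear", {
  r1 <- get_sim(1)
  expect_gt(r1$wss_ratio, 60)
  # order-of-magnitude bands: downstream steady WSS 1-2 Pa,
  # balloon-area peak 50-500 Pa
  expect_gt(r1$tau_physiological, 1)
  expect_lt(r1$tau_physiological, 2)
  expect_gt(r1$peak_tau_max, 50)
  expect_lt(r1$peak_tau_max, 500)
  # the thin-gap phase that carries the WSS peak is within the
  # lubrication validity bound
  expect_lt(r1$re_star_at_peak, 1)
})

test_that("the solution is grid-converged", {
  r1 <- get_sim(1)
  r_fine <- get_sim(1, dt_scale = 0.5, nx_scale = 2)
  expect_lt(abs(r_fine$peak_tau_max - r1$peak_tau_max) / r1$peak_tau_max,
            0.02)
})

test_that("scenario reports align and order the velocity comparisons", {
  r05 <- get_sim(0.5); r1 <- get_sim(1); r2 <- get_sim(2)
  rep3 <- scenario_report(list(r05, r1, r2))
  s <- rep3$summary
  expect_equal(s$multiplier, c(0.5, 1, 2))
  expect_true(all(diff(s$peak_wss_Pa) > 0))
  expect_true(all(diff(s$peak_gap_velocity_m_s) > 0))
  # ratio column is the dimensionless WSS amplification
  expect_equal(s$wss_ratio, s$peak_wss_Pa / s$tau_physiological_Pa)
  # identical inputs give identical rows
  rep_same <- scenario_report(list(r1, r1))
  expect_equal(rep_same$summary[1, ], rep_same$summary[2, ])
  # mismatched geometry is refused
  cfg_big <- simulation_config(geometry = vessel_geometry(R_v = 2))
  r_big <- run_simulation(cfg_big)
  expect_error(scenario_report(list(r1, r_big)), "mismatched")
})
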