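degenerate_spec <- function(arm, n) {
  arm_spec(arm, n,
           continuous = list(age = c(60, 0), tfc_post2 = c(27, 0),
                             ckmb_max = c(300, 0)),
           binary = c(male = 1, no_reflow = 0),
           artery_probs = c(LAD = 0, LCX = 0, RCA = 1),
           timi_pre_probs = c(0, 0, 0, 1))
}

test_that("degenerate distributions reproduce the spec values exactly", {
  coh <- generate_cohort(degenerate_spec("rapid", 4),
                         degenerate_spec("slow", 3), seed = 99)
  p <- coh$patients
  expect_equal(nrow(p), 7)
  expect_true(all(p$age == 60))
  expect_true(all(p$tfc_post2_raw == 27))   # RCA: raw = corrected
  expect_true(all(p$ckmb_max == 300))
  expect_true(all(p$male))
  expect_true(all(!p$no_reflow))
  expect_true(all(p$infarct_artery == "RCA"))
  expect_true(all(!p$occluded_at_baseline))
})

test_that("cohorts are bitwise reproducible under the seed contract", {
  a <- generate_cohort(seed = 5)
  b <- generate_cohort(seed = 5)
  d <- generate_cohort(seed = 6)
  expect_identical(a$patients, b$patients)
  expect_identical(a$enzymes, b$enzymes)
  expect_false(isTRUE(all.equal(a$patients, d$patients)))
  # generation does not disturb the caller's RNG stream
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(generate_cohort(seed = 5)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("frame counts are stored raw and recovered by the correction rule", {
  coh <- generate_cohort(seed = 2)
  p <- coh$patients
  lad <- p$infarct_artery == "LAD"
  corrected <- ctfc(p$tfc_post2_raw, p$infarct_artery, p$occl_post2)
  expect_equal(corrected[lad], p$tfc_post2_raw[lad] / 1.7)
  expect_equal(corrected[!lad], p$tfc_post2_raw[!lad])
  # occluded-at-baseline patients score 100 frames before PCI
  pre <- ctfc(p$tfc_pre_raw, p$infarct_artery, p$occl_pre)
  expect_true(all(pre[p$occluded_at_baseline] == 100))
})

test_that("continuous and binary moments are recovered across replicates", {
  specs <- default_arm_specs()
  R <- 40
  slow_means <- vapply(seq_len(R), function(r) {
    coh <- generate_cohort(specs$rapid, specs$slow, seed = 1000 + r)
    p <- coh$patients[coh$patients$arm == "slow", ]
    mean(ctfc(p$tfc_post2_raw, p$infarct_artery, p$occl_post2))
  }, numeric(1))
  # grand mean within 3 MC standard errors of the 24-frame spec mean
  se <- 7 / sqrt(106 * R)
  expect_lt(abs(mean(slow_means) - 24), 3 * se + 0.05)

  # binary endpoint: pooled no-reflow frequency near 3/106
  pooled <- vapply(seq_len(R), function(r) {
    coh <- generate_cohort(specs$rapid, specs$slow, seed = 2000 + r)
    p <- coh$patients[coh$patients$arm == "slow", ]
    sum(p$no_reflow)
  }, numeric(1))
  p0 <- 3 / 106
  se_b <- sqrt(p0 * (1 - p0) / (106 * R))
  expect_lt(abs(mean(pooled) / 106 - p0), 3 * se_b)
})

test_that("enzyme release curves are unimodal, peaked and schedule-sampled", {
  ser <- generate_ckmb_series(100, peak_time = 12)
  expect_equal(ser$time_h, c(0, 6, 12, 18, 24, 48, 72))
  expect_lte(max(ser$ckmb), 100)
  expect_gte(max(ser$ckmb), 90)        # grid may miss the exact peak
  expect_lte(ser$ckmb[1], 5)           # baseline draw near zero
  # degenerate constant curve: rectangle AUC
  flat <- generate_ckmb_series(50, sigma = Inf)
  expect_equal(auc_trapezoid(flat$time_h, flat$ckmb), 72 * 50)
  expect_error(generate_ckmb_series(-1), "peak_value")
  expect_error(generate_ckmb_series(10, peak_time = 80), "peak_time")
})

test_that("sampled enzyme peaks recover the arm-level peak statistics", {
  # the drawn CK-MB peaks carry the printed slow-arm mean (the
  # truncated-normal location is calibrated, so no truncation bias) and
  # the series maximum equals the drawn peak (12 h lies on the grid)
  specs <- default_arm_specs()
  peaks <- unlist(lapply(1:5, function(r) {
    coh <- generate_cohort(specs$rapid, specs$slow, seed = 5000 + r)
    p <- coh$patients
    series_max <- tapply(coh$enzymes$ckmb, coh$enzymes$patient_id, max)
    expect_equal(as.numeric(series_max[p$patient_id]), p$ckmb_max)
    p$ckmb_max[p$arm == "slow"]
  }))
  expect_lt(abs(mean(peaks) - 272), 3 * 212 / sqrt(length(peaks)))
})

test_that("deflation profiles honour the velocity contract", {
  grid_check <- function(prof) {
    tt <- seq(-0.1, prof$T_deflate + 0.1, by = 1e-3)
    r <- prof$radius(tt)
    expect_true(all(diff(r) <= 1e-12))             # non-increasing
    expect_equal(prof$radius(0), prof$Rb0)
    expect_equal(prof$radius(prof$T_deflate), prof$Rb_min)
    # clamped outside the deflation window
    expect_equal(prof$radius(-5), prof$Rb0)
    expect_equal(prof$radius(prof$T_deflate + 5), prof$Rb_min)
    max(abs(prof$speed(tt)))
  }
  p1 <- generate_deflation_profile(vb = 1.5, multiplier = 1, Rb0 = 1.45)
  p2 <- generate_deflation_profile(vb = 1.5, multiplier = 2, Rb0 = 1.45)
  p05 <- generate_deflation_profile(vb = 1.5, multiplier = 0.5, Rb0 = 1.45)
  expect_equal(grid_check(p1), 1.5, tolerance = 0.01)
  expect_equal(grid_check(p2), 3.0, tolerance = 0.01)
  expect_equal(grid_check(p05), 0.75, tolerance = 0.01)
  # doubling the multiplier halves the deflation time
  expect_equal(p2$T_deflate, p1$T_deflate / 2, tolerance = 1e-10)
})

test_that("protocol-paced profiles and geometry guards work", {
  geo <- vessel_geometry()
  # slow mode: 16 atm bled at 2 atm/s -> 8 s deflation
  prof <- generate_deflation_profile(
    protocol = deflation_protocol("slow", start_pressure = 16,
                                  slow_rate = 2),
    geometry = geo)
  expect_equal(prof$T_deflate, 8, tolerance = 1e-10)
  # rapid mode compresses the same excursion into rapid_duration
  prof_r <- generate_deflation_profile(
    protocol = deflation_protocol("rapid", rapid_duration = 0.5),
    geometry = geo)
  expect_equal(prof_r$T_deflate, 0.5, tolerance = 1e-10)
  expect_equal(prof_r$Rb0, prof$Rb0)
  expect_error(generate_deflation_profile(geometry = geo, Rb0 = 1.6),
               "geometry")
})

test_that("arm specifications validate their fields by name", {
  expect_error(arm_spec("rapid", 0), "`n`")
  expect_error(arm_spec("fast", 10), "arm_label")
  expect_error(arm_spec("rapid", 10, continuous = list(age = c(60, -1))),
               "continuous\\$age")
  expect_error(arm_spec("rapid", 10, binary = c(male = 1.2)),
               "binary\\$male")
  expect_error(arm_spec("rapid", 10,
                        event_hazards = c(death = -0.1)),
               "event_hazards\\$death")
})

test_that("cohorts round-trip through the CSV writer", {
  coh <- generate_cohort(seed = 3)
  dir <- withr_like_tempdir <- file.path(tempdir(), "coh-rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$patients)[, names(coh$patients)],
               as.data.frame(coh$patients), tolerance = 1e-12)
  expect_equal(back$enzymes$ckmb, coh$enzymes$ckmb, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
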