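#' Specify the distributional structure of one trial arm
#'
#' An `arm_spec` holds everything the synthetic-cohort generator needs
#' for one randomization arm: the arm size, per-endpoint mean/SD pairs
#' for continuous endpoints (drawn as zero-truncated normals), event
#' probabilities for binary endpoints, categorical distributions for the
#' infarct-related artery, baseline TIMI grade and Killip class, the
#' enzyme-release curve parameters, and daily hazards for the 30-day
#' adverse events.
#'
#' @param arm_label `"rapid"` or `"slow"`.
#' @param n number of subjects in the arm.
#' @param continuous named list; each element `c(mean, sd)` in the
#'   endpoint's natural units (frames for frame counts, U/L for CK/CK-MB,
#'   ng/mL for troponin, years for age, ...).
#' @param binary named numeric vector of event probabilities in `[0, 1]`.
#' @param artery_probs probabilities for `c(LAD, LCX, RCA)`, summing to 1.
#' @param timi_pre_probs probabilities for baseline TIMI flow grades 0-3.
#' @param killip_probs probabilities for Killip classes I-IV.
#' @param enzyme list with `peak_time_h`, `sigma`, `sample_times_h`,
#'   `noise_sd` controlling the CK-MB release curve (see
#'   [generate_ckmb_series()]).
#' @param event_hazards named numeric vector of constant daily hazards
#'   for the 30-day events (`death`, `heart_failure`,
#'   `myocardial_infarction`, `revascularization`, `rehospitalization`).
#' @param followup_days administrative censoring time (days).
#' @return An object of class `arm_spec`.
#' @seealso [default_arm_specs()], [generate_cohort()]
#' @export
arm_spec <- function(arm_label, n, continuous = list(), binary = numeric(),
                     artery_probs = c(LAD = 1 / 3, LCX = 1 / 3, RCA = 1 / 3),
                     timi_pre_probs = c(1, 0, 0, 0),
                     killip_probs = c(1, 0, 0, 0),
                     enzyme = list(peak_time_h = 12, sigma = 0.8,
                                   sample_times_h = c(0, 6, 12, 18, 24, 48, 72),
                                   noise_sd = 0),
                     event_hazards = numeric(),
                     followup_days = 30) {
  spec <- structure(
    list(arm_label = arm_label, n = n, continuous = continuous,
         binary = binary, artery_probs = artery_probs,
         timi_pre_probs = timi_pre_probs, killip_probs = killip_probs,
         enzyme = enzyme, event_hazards = event_hazards,
         followup_days = followup_days),
    class = "arm_spec")
  validate_arm_spec(spec)
  spec
}

#' @rdname arm_spec
#' @param spec an `arm_spec` to validate.
#' @export
validate_arm_spec <- function(spec) {
  check_that(inherits(spec, "arm_spec"), "spec", "not an arm_spec")
  check_that(spec$arm_label %in% c("rapid", "slow"), "arm_label",
             "must be \"rapid\" or \"slow\"")
  check_that(is.numeric(spec$n) && length(spec$n) == 1 && spec$n > 0 &&
               spec$n == round(spec$n), "n", "must be a positive integer")
  for (nm in names(spec$continuous)) {
    v <- spec$continuous[[nm]]
    check_that(is.numeric(v) && length(v) == 2 && is.finite(v[1]) &&
                 v[2] >= 0, paste0("continuous$", nm),
               "must be c(mean, sd) with sd >= 0")
  }
  if (length(spec$binary)) {
    bad <- names(spec$binary)[spec$binary < 0 | spec$binary > 1 |
                                !is.finite(spec$binary)]
    check_that(length(bad) == 0, paste0("binary$", bad[1]),
               "probability must lie in [0, 1]")
  }
  for (nm in c("artery_probs", "timi_pre_probs", "killip_probs")) {
    p <- spec[[nm]]
    check_that(all(p >= 0) && abs(sum(p) - 1) < 1e-4, nm,
               "must be non-negative and sum to 1")
  }
  if (length(spec$event_hazards)) {
    bad <- names(spec$event_hazards)[spec$event_hazards < 0]
    check_that(length(bad) == 0, paste0("event_hazards$", bad[1]),
               "hazard must be >= 0")
  }
  check_that(spec$followup_days > 0 && spec$followup_days <= 30,
             "followup_days", "must lie in (0, 30]")
  invisible(spec)
}

#' Default arm specifications for the balloon-deflation trial
#'
#' Reads the shipped `trial.cfg` and returns the pair of [arm_spec()]
#' objects encoding the printed arm-level summaries of the two-arm
#' randomized deflation-velocity trial (n = 105 rapid / 106 slow):
#' baseline covariates, angiographic and procedural endpoints, corrected
#' TIMI frame counts at four timepoints, peak enzyme statistics, and
#' 30-day event proportions (converted to constant daily hazards
#' \eqn{\lambda = -\log(1 - p)/30}).
#'
#' @param path optional path to an alternative trial configuration file.
#' @return Named list with elements `rapid` and `slow`.
#' @examples
#' specs <- default_arm_specs()
#' specs$slow$continuous$tfc_post2   # mean 24, sd 7 frames
#' @export
default_arm_specs <- function(path = default_config_paths()[["trial"]]) {
  cfg <- read_config(path)
  fu <- if (!is.null(cfg$followup$days)) cfg$followup$days else 30
  one <- function(arm) {
    p30 <- unlist(cfg[[paste0(arm, ".events")]])
    arm_spec(
      arm_label = arm,
      n = cfg[[arm]]$n,
      continuous = cfg[[paste0(arm, ".continuous")]],
      binary = unlist(cfg[[paste0(arm, ".binary")]]),
      artery_probs = unlist(cfg[[paste0(arm, ".artery")]]),
      timi_pre_probs = unlist(cfg[[paste0(arm, ".timi_pre")]]),
      killip_probs = unlist(cfg[[paste0(arm, ".killip")]]),
      enzyme = cfg$enzyme,
      event_hazards = -log(1 - pmin(p30, 1 - 1e-12)) / fu,
      followup_days = fu)
  }
  list(rapid = one("rapid"), slow = one("slow"))
}

#' @export
print.arm_spec <- function(x, ...) {
  cat(sprintf("<arm_spec> %s arm, n = %d\n", x$arm_label, x$n))
  cat(sprintf("  %d continuous endpoints, %d binary, %d event hazards\n",
              length(x$continuous), length(x$binary),
              length(x$event_hazards)))
  invisible(x)
}
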