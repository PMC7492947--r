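# 30-day major-adverse-cardiac-event (MACE) endpoints: first-event
# composite and Kaplan-Meier curves.

#' First-event MACE composite from patient records
#'
#' The MACE composite is death, myocardial infarction,
#' revascularization, heart failure or rehospitalization within 30
#' days.  Each patient contributes the time of their first qualifying
#' event, or their censoring time (`followup_days`) with no event.
#'
#' @param patients the `patients` tibble of a `trial_cohort` (or a
#'   `trial_cohort` itself), with `day_<event>` columns.
#' @param events optional long-format event listing (`patient_id`,
#'   `event`, `day`) overriding the `day_*` columns; event names must
#'   belong to the five MACE categories, otherwise an error is raised.
#' @return A tibble (`patient_id`, `arm`, `time`, `event`) -- one row
#'   per patient, `time` in days, `event` logical -- with a
#'   `category_counts` attribute holding the per-category, per-arm
#'   event counts.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' mc <- mace_composite(coh)
#' attr(mc, "category_counts")
#' @export
mace_composite <- function(patients, events = NULL) {
  if (inherits(patients, "trial_cohort")) patients <- patients$patients
  if (!is.null(events)) {
    bad <- setdiff(unique(events$event), MACE_EVENTS)
    if (length(bad)) {
      stop("unknown event name(s): ", paste(bad, collapse = ", "),
           "; MACE categories are ", paste(MACE_EVENTS, collapse = ", "),
           call. = FALSE)
    }
    for (ev in MACE_EVENTS) {
      d <- events$day[events$event == ev]
      id <- events$patient_id[events$event == ev]
      patients[[paste0("day_", ev)]] <-
        d[match(patients$patient_id, id)]
    }
  }
  cols <- paste0("day_", MACE_EVENTS)
  missing_cols <- setdiff(cols, names(patients))
  for (cl in missing_cols) patients[[cl]] <- NA_real_
  days <- as.matrix(patients[cols])
  first <- suppressWarnings(apply(days, 1, min, na.rm = TRUE))
  has_event <- is.finite(first)
  fu <- if (!is.null(patients$followup_days)) patients$followup_days else 30
  out <- tibble(patient_id = patients$patient_id,
                arm = patients$arm,
                time = ifelse(has_event, first, fu),
                event = has_event)
  counts <- do.call(rbind, lapply(MACE_EVENTS, function(ev) {
    d <- patients[[paste0("day_", ev)]]
    tibble(event = ev,
           rapid = sum(!is.na(d) & patients$arm == "rapid"),
           slow = sum(!is.na(d) & patients$arm == "slow"))
  }))
  attr(out, "category_counts") <- counts
  out
}

#' Kaplan-Meier curve of freedom from MACE
#'
#' Product-limit estimator per arm with right-censoring, computed with
#' the survival package.  The returned object carries a tidy step table
#' and can be evaluated at any time in the follow-up window with
#' [km_survival_at()].
#'
#' @param time event/censoring times (days), in (0, 30].
#' @param event logical or 0/1 event indicator.
#' @param arm arm labels (`"rapid"`/`"slow"` or any factor).
#' @return An object of class `km_curve`: list with the `survfit` fit,
#'   a tidy `table` (`arm`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`), and per-arm totals `events`/`n`.
#' @examples
#' mc <- mace_composite(generate_cohort(seed = 1))
#' km <- km_curve(mc$time, mc$event, mc$arm)
#' km_survival_at(km, 30)
#' @export
km_curve <- function(time, event, arm = rep("all", length(time))) {
  check_that(is.numeric(time) && all(time > 0), "time",
             "event/censoring times must be positive")
  event <- as.logical(event)
  arm <- as.character(arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm,
                           data = data.frame(time = time, event = event,
                                             arm = arm))
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(unique(arm), length(sm$time)) else {
    sub("^arm=", "", as.character(sm$strata))
  }
  tab <- tibble(arm = strata, time = sm$time, n_risk = sm$n.risk,
                n_event = sm$n.event, n_censor = sm$n.censor,
                surv = sm$surv)
  structure(list(fit = fit, table = tab,
                 events = vapply(split(event, arm), sum, numeric(1)),
                 n = vapply(split(event, arm), length, numeric(1))),
            class = "km_curve")
}

#' @rdname km_curve
#' @param km a `km_curve`.
#' @param t time(s) in days at which to evaluate the step function.
#' @return `km_survival_at()`: a tibble (`arm`, `t`, `surv`); survival
#'   is 1 before the first event.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"))
  out <- lapply(unique(km$table$arm), function(a) {
    sub <- km$table[km$table$arm == a & km$table$n_event > 0, ]
    s <- if (nrow(sub) == 0) rep(1, length(t)) else {
      stats::stepfun(sub$time, c(1, sub$surv), right = FALSE)(t)
    }
    tibble(arm = a, t = t, surv = s)
  })
  do.call(rbind, out)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>\n")
  for (a in names(x$n)) {
    cat(sprintf("  %s: %d events / %d subjects\n", a, x$events[[a]],
                x$n[[a]]))
  }
  invisible(x)
}
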