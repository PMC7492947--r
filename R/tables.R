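# Endpoint summaries: Tables 1-5 analogues for a synthetic cohort.

#' No-reflow flag from procedural TIMI grades
#'
#' No-reflow is defined as culprit-artery flow below TIMI grade 2
#' during or at the end of the procedure.
#'
#' @param patients the `patients` tibble of a `trial_cohort` (or the
#'   cohort itself) carrying the procedural grades `timi_post1` and
#'   `timi_post2`.
#' @return Logical vector, one element per patient.
#' @export
no_reflow_flag <- function(patients) {
  if (inherits(patients, "trial_cohort")) patients <- patients$patients
  need <- c("timi_post1", "timi_post2")
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols)) {
    stop("missing procedural TIMI grade(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  g <- as.matrix(patients[need])
  if (anyNA(g)) stop("missing TIMI grade values", call. = FALSE)
  apply(g < 2, 1, any)
}

# schema of reported endpoints; `get` pulls the per-patient values
endpoint_schema <- function() {
  cont <- function(tab, label, col) {
    list(table = tab, endpoint = label, type = "continuous",
         get = function(p) p[[col]])
  }
  bin <- function(tab, label, col) {
    list(table = tab, endpoint = label, type = "binary",
         get = function(p) as.logical(p[[col]]))
  }
  ctfc_at <- function(tab, label, tp) {
    list(table = tab, endpoint = label, type = "continuous",
         get = function(p) ctfc(p[[paste0("tfc_", tp, "_raw")]],
                                p$infarct_artery,
                                p[[paste0("occl_", tp)]]))
  }
  c(
    list(cont(1, "Age (years)", "age"), bin(1, "Male", "male"),
         cont(1, "BMI (kg/m2)", "bmi"), cont(1, "SBP (mmHg)", "sbp"),
         cont(1, "DBP (mmHg)", "dbp"),
         cont(1, "Oxygen saturation (%)", "spo2"),
         cont(1, "Hemoglobin (g/L)", "hemoglobin"),
         cont(1, "BNP (pg/mL)", "bnp"),
         bin(1, "Hypertension", "hypertension"),
         bin(1, "Hyperlipidemia", "hyperlipidemia"),
         bin(1, "Diabetes", "diabetes"), bin(1, "Smoking", "smoking"),
         cont(1, "eGFR (mL/min/1.73m2)", "egfr")),
    lapply(c("LAD", "LCX", "RCA"), function(v) {
      list(table = 2, endpoint = paste("Infarct-related artery:", v),
           type = "binary", get = function(p) p$infarct_artery == v)
    }),
    list(list(table = 2, endpoint = "Killip class I", type = "binary",
              get = function(p) p$killip == "I"),
         cont(2, "Symptom to FMC (h)", "symptom_to_fmc_h"),
         cont(2, "Door to balloon (min)", "door_to_balloon_min")),
    list(cont(3, "Target lesion length (mm)", "lesion_length_mm"),
         cont(3, "Proximal reference (mm)", "proximal_ref_mm"),
         cont(3, "Distal reference (mm)", "distal_ref_mm"),
         cont(3, "Number of stents", "n_stents"),
         cont(3, "Inflation pressure (atm)", "inflation_atm"),
         bin(3, "Predilation", "predilation"),
         bin(3, "Postdilation", "postdilation"),
         bin(3, "Thrombus aspiration", "thrombus_aspiration"),
         bin(3, "Tirofiban", "tirofiban"),
         bin(3, "Aspirin + ticagrelor", "ticagrelor"),
         bin(3, "ACEI/ARB", "acei_arb"), bin(3, "Statins", "statins"),
         bin(3, "Beta-blockers", "beta_blockers"),
         bin(3, "Oral anticoagulation", "oral_anticoagulation")),
    list(bin(4, "TIMI grade 0 before PCI", "occluded_at_baseline"),
         ctfc_at(4, "cTFC before PCI (frames)", "pre"),
         ctfc_at(4, "cTFC before stenting (frames)", "prestent"),
         ctfc_at(4, "cTFC post stent (frames)", "post1"),
         ctfc_at(4, "cTFC end of PCI (frames)", "post2"),
         cont(4, "CK max (U/L)", "ck_max"),
         cont(4, "CK-MB max (U/L)", "ckmb_max"),
         cont(4, "TNI max (ng/mL)", "tni_max"),
         list(table = 4, endpoint = "No-reflow", type = "binary",
              get = function(p) no_reflow_flag(p)),
         cont(4, "LVEF at 7 days (%)", "lvef")),
    Map(function(label, ev) {
      force(ev)
      list(table = 5, endpoint = label, type = "binary",
           get = function(p) !is.na(p[[paste0("day_", ev)]]))
    },
    c("Mortality", "Heart failure", "Myocardial infarction",
      "Target vessel/lesion revascularization", "Rehospitalization"),
    c("death", "heart_failure", "myocardial_infarction",
      "revascularization", "rehospitalization"))
  )
}

compare_binary <- function(x_rapid, x_slow) {
  tab <- c(sum(x_rapid), sum(!x_rapid), sum(x_slow), sum(!x_slow))
  m <- matrix(tab, 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected >= 5)) {
    list(p = chi_square_2x2(tab)$p_value, test = "chi-square")
  } else {
    list(p = fisher_exact_2x2(tab), test = "exact")
  }
}

#' Arm-comparison tables for a trial cohort
#'
#' Computes the five standard trial report tables (baseline,
#' angiographic, procedural, coronary flow / infarct size, 30-day
#' events) for a cohort: continuous endpoints as mean +/- SD compared
#' by Welch t-test; binary endpoints as n (%) compared by Pearson
#' chi-square when every expected cell is at least 5, otherwise by the
#' exact test.  Every test selection is logged.
#'
#' @param cohort a `trial_cohort` (or its `patients` tibble).
#' @return List `table1` ... `table5` of tibbles (`endpoint`, `type`,
#'   numeric per-arm summaries, formatted `rapid`/`slow` labels,
#'   `p_value`, `test`) plus a `log` tibble of test choices.
#' @examples
#' tabs <- build_tables(generate_cohort(seed = 1))
#' tabs$table5
#' @export
build_tables <- function(cohort) {
  patients <- if (inherits(cohort, "trial_cohort")) cohort$patients else cohort
  check_that(all(c("rapid", "slow") %in% patients$arm), "cohort",
             "both arms must be non-empty")
  is_rapid <- patients$arm == "rapid"
  rows <- lapply(endpoint_schema(), function(e) {
    v <- e$get(patients)
    vr <- v[is_rapid]; vs <- v[!is_rapid]
    if (e$type == "continuous") {
      tt <- suppressMessages(
        two_sample_t(summary_stat(mean(vr), stats::sd(vr), length(vr)),
                     summary_stat(mean(vs), stats::sd(vs), length(vs))))
      tibble(table = e$table, endpoint = e$endpoint, type = e$type,
             rapid_mean = mean(vr), rapid_sd = stats::sd(vr),
             slow_mean = mean(vs), slow_sd = stats::sd(vs),
             rapid_events = NA_integer_, slow_events = NA_integer_,
             rapid = sprintf("%.1f ± %.1f", mean(vr), stats::sd(vr)),
             slow = sprintf("%.1f ± %.1f", mean(vs), stats::sd(vs)),
             p_value = tt$p_value, test = tt$method)
    } else {
      cmp <- compare_binary(vr, vs)
      tibble(table = e$table, endpoint = e$endpoint, type = e$type,
             rapid_mean = NA_real_, rapid_sd = NA_real_,
             slow_mean = NA_real_, slow_sd = NA_real_,
             rapid_events = sum(vr), slow_events = sum(vs),
             rapid = sprintf("%d (%.1f)", sum(vr), 100 * mean(vr)),
             slow = sprintf("%d (%.1f)", sum(vs), 100 * mean(vs)),
             p_value = cmp$p, test = cmp$test)
    }
  })
  all_rows <- do.call(rbind, rows)
  out <- lapply(1:5, function(k) {
    tb <- all_rows[all_rows$table == k, ]
    tb$table <- NULL
    tb
  })
  names(out) <- paste0("table", 1:5)
  out$log <- all_rows[, c("table", "endpoint", "type", "test")]
  out
}
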