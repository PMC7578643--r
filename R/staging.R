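#' SIRS screening thresholds
#'
#' Thresholds of the systemic inflammatory response syndrome criteria used by
#' the sepsis-2.0 eligibility screen: temperature at or below `temp_low` or at
#' or above `temp_high`; heart rate at or above `hr_min`; respiratory rate at
#' or above `rr_min` or PaCO2 below `paco2_max`; white cell count above
#' `wbc_high` or below `wbc_low` or band percentage above `band_pct_min`.
#' Eligibility requires suspected/documented infection plus at least
#' `criteria_required` criteria.
#'
#' @return Named list of thresholds, class `dtr_sirs_thresholds`.
#' @export
sirs_thresholds <- function() {
  structure(
    list(temp_low = 36, temp_high = 38, hr_min = 90, rr_min = 20,
         paco2_max = 32, wbc_high = 12000, wbc_low = 4000,
         band_pct_min = 10, criteria_required = 2L),
    class = "dtr_sirs_thresholds"
  )
}

#' Sepsis-2.0 eligibility screen
#'
#' Counts the SIRS criteria satisfied by a daily record and combines the count
#' with the infection flag. Missing WBC or PaCO2 values degrade the
#' corresponding criterion to not-met; they never abort the screen.
#'
#' @param record Named list or one-row data frame with fields `temp`, `hr`,
#'   `rr` (required) and optionally `paco2`, `wbc`, `band_pct`.
#' @param infection Logical: suspected or documented infection.
#' @param thresholds A [sirs_thresholds()] object.
#' @return Logical scalar with attributes `criteria` (number met).
#' @export
screen_sirs <- function(record, infection, thresholds = sirs_thresholds()) {
  need <- c("temp", "hr", "rr")
  have <- vapply(need, function(v) !is.null(record[[v]]) && !is.na(record[[v]]),
                 logical(1))
  if (!all(have)) {
    stop_missing(paste("screen_sirs: required vitals missing:",
                       paste(need[!have], collapse = ", ")))
  }
  th <- thresholds
  val <- function(v) {
    x <- record[[v]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }
  met_or_na <- function(x) !is.na(x) & x  # missing component -> not met
  c_temp <- record$temp <= th$temp_low || record$temp >= th$temp_high
  c_hr   <- record$hr >= th$hr_min
  c_resp <- record$rr >= th$rr_min || met_or_na(val("paco2") < th$paco2_max)
  c_wbc  <- met_or_na(val("wbc") > th$wbc_high) ||
            met_or_na(val("wbc") < th$wbc_low) ||
            met_or_na(val("band_pct") > th$band_pct_min)
  n_met <- sum(c_temp, c_hr, c_resp, c_wbc)
  out <- isTRUE(infection) && n_met >= th$criteria_required
  structure(out, criteria = n_met)
}

#' Dichotomize daily fluid intake
#'
#' Daily fluid intake of 40 ml/kg/day or more is the liberal strategy;
#' anything below is restricted.
#'
#' @param intake Numeric vector, ml/kg/day; must be nonnegative.
#' @return Integer vector: 1 = liberal, 0 = restricted.
#' @export
dichotomize_fluid <- function(intake) {
  if (any(is.na(intake))) stop_invalid("fluid intake contains missing values")
  if (any(intake < 0)) stop_invalid("fluid intake must be nonnegative")
  as.integer(intake >= 40)
}

# Per-patient first-row summary of a validated cohort table.
cohort_patients <- function(cohort) {
  first <- !duplicated(cohort$patient_id)
  data.frame(
    patient_id = cohort$patient_id[first],
    age = cohort$age[first],
    icu_type = cohort$icu_type[first],
    death_time = cohort$death_time[first],
    discharge_time = cohort$discharge_time[first],
    status = cohort$status[first],
    stringsAsFactors = FALSE
  )
}

outcome_time <- function(patients) {
  ifelse(patients$status == "died", patients$death_time,
         patients$discharge_time)
}

#' Build per-stage survival records
#'
#' Converts a patient-day cohort table into the three-stage decision
#' structure. Stage 1 spans days 1-2 (time 0 to 2 from ICU admission),
#' stage 2 days 3-4 (time 2 to 4), stage 3 day 5 onwards (open-ended).
#' A patient enters stage k+1 if still in the ICU (neither dead nor
#' discharged) at the stage boundary. The stage treatment `a` is the fluid
#' strategy of the decision day (1, 3 or 5); `event` flags death within the
#' stage, `censored` alive discharge within the stage, and `death` the
#' patient's final vital status (used by the censoring weights).
#'
#' @param cohort A cohort data frame as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @return Data frame of class `dtr_stage_records`, one row per entered
#'   patient-stage, with columns `patient_id`, `stage`, `entered`, `a`, `T`,
#'   `event`, `censored`, `death`.
#' @export
stage_records <- function(cohort) {
  validate_cohort(cohort)
  pts <- cohort_patients(cohort)
  tout <- outcome_time(pts)
  if (any(is.na(tout)) || any(tout <= 0)) {
    bad <- pts$patient_id[is.na(tout) | tout <= 0]
    stop_malformed(paste("nonpositive or missing outcome time for patient(s):",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  died <- pts$status == "died"
  fluid_at <- function(ids, day) {
    i <- match(paste(ids, day), paste(cohort$patient_id, cohort$day))
    if (anyNA(i)) {
      bad <- ids[is.na(i)]
      stop_malformed(sprintf(
        "missing day-%d fluid record for patient(s): %s", day,
        paste(utils::head(bad, 5), collapse = ", ")))
    }
    dichotomize_fluid(cohort$fluid_ml_per_kg[i])
  }
  rows <- list()
  for (k in 1:3) {
    start <- 2 * (k - 1)
    ent <- tout > start
    if (!any(ent)) next
    ids <- pts$patient_id[ent]
    tk <- tout[ent] - start
    if (k < 3) {
      ev <- died[ent] & tk <= 2
      cs <- !died[ent] & tk <= 2
      tk <- pmin(tk, 2)
    } else {
      ev <- died[ent]
      cs <- !died[ent]
    }
    rows[[k]] <- data.frame(
      patient_id = ids, stage = k, entered = TRUE,
      a = fluid_at(ids, decision_day(k)),
      T = tk, event = as.integer(ev), censored = as.integer(cs),
      death = as.integer(died[ent]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dtr_stage_records", "data.frame")
  out
}

#' Assemble raw stage features from a cohort table
#'
#' Collects, for each requested patient, every raw variable/day pair demanded
#' by a stage's model specification, as a feature table with `"<var>_<day>"`
#' columns (plus `age`, `icu_type` for time-constant variables). The daily
#' fluid strategy variable `fluid` is derived from `fluid_ml_per_kg` via
#' [dichotomize_fluid()]; urine output is read from `urine_ml`. A required
#' value missing for any patient raises a missing-data error naming the
#' variable and day.
#'
#' @param cohort Cohort data frame.
#' @param stage Stage index 1-3 (used only for error messages).
#' @param spec A [model_spec()] for the stage, or a plain list of
#'   [term_spec()] objects.
#' @param ids Patient ids to assemble; defaults to all patients.
#' @return Data frame with `patient_id` and one column per required feature.
#' @export
assemble_features <- function(cohort, stage, spec, ids = NULL) {
  pts <- cohort_patients(cohort)
  if (is.null(ids)) ids <- pts$patient_id
  terms <- if (inherits(spec, "dtr_model_spec")) {
    c(spec$blip, spec$treatment_free)
  } else spec
  pairs <- unique(do.call(rbind, lapply(terms, function(t) {
    if (t$transform == "product") return(NULL)
    data.frame(var = t$var, day = t$day, stringsAsFactors = FALSE)
  })))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  if (is.null(pairs) || !nrow(pairs)) return(out)
  key <- paste(cohort$patient_id, cohort$day)
  for (i in seq_len(nrow(pairs))) {
    var <- pairs$var[i]; day <- pairs$day[i]
    if (is.na(day)) {
      j <- match(ids, pts$patient_id)
      out[[var]] <- pts[[var]][j]
    } else {
      j <- match(paste(ids, day), key)
      if (anyNA(j)) {
        bad <- ids[is.na(j)]
        stop_missing(sprintf(
          "stage %d: variable '%s' on day %d missing for patient(s): %s",
          stage, var, day, paste(utils::head(bad, 5), collapse = ", ")))
      }
      col <- switch(var, urine = "urine_ml", fluid = "fluid_ml_per_kg", var)
      x <- cohort[[col]][j]
      if (is.null(x)) {
        stop_missing(sprintf("stage %d: cohort has no column for variable '%s'",
                             stage, var))
      }
      if (any(is.na(x))) {
        bad <- ids[is.na(x)]
        stop_missing(sprintf(
          "stage %d: variable '%s' on day %d is NA for patient(s): %s",
          stage, var, day, paste(utils::head(bad, 5), collapse = ", ")))
      }
      if (var == "fluid") x <- dichotomize_fluid(x)
      out[[paste0(var, "_", day)]] <- x
    }
  }
  out
}
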