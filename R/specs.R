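#' ICU unit-type labels
#'
#' The eight unit types carried by the cohort table. `CCU-CTICU` is the
#' reference level of the day-1 decision rule's unit-type indicators.
#'
#' @return Character vector of length 8.
#' @export
icu_levels <- function() {
  c("CCU-CTICU", "CSICU", "CTICU", "Cardiac ICU",
    "MICU", "Med-Surg ICU", "Neuro ICU", "SICU")
}

icu_indicator_terms <- function(day = NA_integer_) {
  lv <- setdiff(icu_levels(), "CCU-CTICU")
  nm <- gsub("[ -]", "", lv)
  mapply(function(l, n) term_spec(n, "icu_type", day = day,
                                  transform = "indicator", level = l),
         lv, nm, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Default three-stage model specifications
#'
#' The default candidate terms mirror the structure of the published
#' fluid-management rules: the day-1 blip carries age, unit-type indicators,
#' heart rate and mean blood pressure on a per-20 scale with a quadratic mBP
#' term, and mechanical ventilation; the day-3 blip carries temperature, mBP,
#' urine output of the two previous days (per 1000 ml), ventilation and the
#' day-1/day-2 fluid strategies; the day-5 blip carries ventilation, unscaled
#' heart rate and mBP, and the day-3/day-4 fluid strategies with their
#' interaction (the day-5 blip is kept to near-balanced binary history
#' terms; unscaled HR and mBP enter its treatment-free part). The
#' treatment-free part otherwise shares the candidate pool. Age and mBP
#' terms are flagged `forced` so backward elimination retains them.
#'
#' @return List of three [model_spec()] objects, class `dtr_specs`.
#' @export
default_specs <- function() {
  s1 <- model_spec(1, blip = c(
    list(term_spec("Age", "age", transform = "identity", forced = TRUE)),
    icu_indicator_terms(),
    list(
      term_spec("HR1", "hr", 1, "scale", scale = 20),
      term_spec("MBP1", "mbp", 1, "scale", scale = 20, forced = TRUE),
      term_spec("MBP1sq", "mbp", 1, "scalesq", scale = 20, forced = TRUE),
      term_spec("MV1", "mv", 1, "identity")
    )))
  s2 <- model_spec(2, blip = list(
    term_spec("Temp3", "temp", 3, "identity"),
    term_spec("MBP3", "mbp", 3, "scale", scale = 20, forced = TRUE),
    term_spec("Urine2", "urine", 2, "scale", scale = 1000),
    term_spec("Urine1", "urine", 1, "scale", scale = 1000),
    term_spec("MV3", "mv", 3, "identity"),
    term_spec("Fluid2", "fluid", 2, "identity"),
    term_spec("Fluid1", "fluid", 1, "identity")
  ))
  s3 <- model_spec(3, blip = list(
    term_spec("MV5", "mv", 5, "identity"),
    term_spec("Fluid3", "fluid", 3, "identity"),
    term_spec("Fluid4", "fluid", 4, "identity"),
    term_spec("Fluid34", "fluid", 4, "product",
              parents = c("Fluid3", "Fluid4"))
  ), treatment_free = list(
    term_spec("MV5", "mv", 5, "identity"),
    term_spec("HR5", "hr", 5, "identity"),
    term_spec("MBP5", "mbp", 5, "identity"),
    term_spec("Fluid3", "fluid", 3, "identity"),
    term_spec("Fluid4", "fluid", 4, "identity"),
    term_spec("Fluid34", "fluid", 4, "product",
              parents = c("Fluid3", "Fluid4"))
  ))
  structure(list(s1, s2, s3), class = "dtr_specs")
}

#' @export
print.dtr_specs <- function(x, ...) {
  cat("Three-stage DTR model specifications\n")
  for (s in x) print(s)
  invisible(x)
}
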