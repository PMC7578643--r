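# Shared fixtures, built in code.

# A three-patient hand-written cohort covering the canonical outcome paths:
# A dies mid stage 1, B dies early in stage 3, C is discharged alive during
# stage 3.
toy_cohort <- function() {
  row <- function(pid, day, age, icu, hr, mbp, rr, temp, urine, mv, vaso,
                  fluid, death, disch, status) {
    data.frame(patient_id = pid, day = day, age = age, icu_type = icu,
               hr = hr, mbp = mbp, rr = rr, temp = temp, urine_ml = urine,
               mv = mv, vasopressor = vaso, fluid_ml_per_kg = fluid,
               death_time = death, discharge_time = disch, status = status,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("A", 1, 70, "MICU", 120, 50, 25, 38.2, 400, 1, 1, 45,   1.5, NA, "died"),
    row("A", 2, 70, "MICU", 118, 52, 24, 38.0, 350, 1, 1, 30,   1.5, NA, "died"),

    row("B", 1, 60, "SICU", 100, 60, 22, 37.1, 800, 0, 0, 38.88, 4.2, NA, "died"),
    row("B", 2, 60, "SICU", 102, 58, 21, 37.0, 900, 0, 0, 50,    4.2, NA, "died"),
    row("B", 3, 60, "SICU",  99, 61, 20, 36.9, 850, 0, 0, 39.999,4.2, NA, "died"),
    row("B", 4, 60, "SICU",  97, 63, 19, 36.8, 800, 0, 0, 40,    4.2, NA, "died"),
    row("B", 5, 60, "SICU",  96, 64, 19, 36.8, 780, 0, 0, 10,    4.2, NA, "died"),

    row("C", 1, 55, "CCU-CTICU", 90, 70, 18, 36.5, 1200, 0, 0, 20, NA, 6, "discharged_alive"),
    row("C", 2, 55, "CCU-CTICU", 92, 71, 18, 36.6, 1300, 0, 0, 55, NA, 6, "discharged_alive"),
    row("C", 3, 55, "CCU-CTICU", 91, 72, 19, 36.6, 1250, 0, 0, 41, NA, 6, "discharged_alive"),
    row("C", 4, 55, "CCU-CTICU", 90, 70, 18, 36.5, 1200, 0, 0, 39, NA, 6, "discharged_alive"),
    row("C", 5, 55, "CCU-CTICU", 89, 69, 18, 36.4, 1100, 0, 0, 60, NA, 6, "discharged_alive")
  )
}

# Minimal dtr_nuisance stand-in with fixed fitted probabilities.
fake_nuisance <- function(pi, K) {
  structure(list(propensity = NULL, censoring = NULL, pi = pi, K = K),
            class = "dtr_nuisance")
}

# Reduced stage-1 style spec without the rare unit-type indicators, for
# small-sample fitting tests.
small_spec1 <- function(extra = NULL) {
  blip <- list(
    term_spec("Age", "age", transform = "identity", forced = TRUE),
    term_spec("HR1", "hr", 1, "scale", scale = 20),
    term_spec("MBP1", "mbp", 1, "scale", scale = 20, forced = TRUE),
    term_spec("MBP1sq", "mbp", 1, "scalesq", scale = 20, forced = TRUE),
    term_spec("MV1", "mv", 1, "identity")
  )
  model_spec(1, blip = c(blip, extra))
}

# Ground-truth blip scores for one stage of a simulated cohort.
true_blip_scores <- function(cohort, params, stage, ids) {
  feats <- assemble_features(cohort, stage, params$specs[[stage]], ids = ids)
  drop(term_matrix(params$specs[[stage]]$blip, feats) %*%
         params$psi_star[[stage]])
}
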