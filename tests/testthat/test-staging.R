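test_that("SIRS screen counts criteria and requires infection", {
  th <- sirs_thresholds()
  # fever + tachycardia only
  r <- list(temp = 38.5, hr = 95, rr = 18, wbc = 8000)
  out <- screen_sirs(r, infection = TRUE, th)
  expect_true(out)
  expect_identical(attr(out, "criteria"), 2L)
  # normal vitals, no infection
  r2 <- list(temp = 37, hr = 70, rr = 14, wbc = 8000, paco2 = 40)
  expect_false(screen_sirs(r2, infection = FALSE, th))
  # boundary values sit on the eligible side of every printed inequality
  r3 <- list(temp = 36.0, hr = 90, rr = 20, wbc = 12001)
  out3 <- screen_sirs(r3, infection = TRUE, th)
  expect_true(out3)
  expect_identical(attr(out3, "criteria"), 4L)
  # missing WBC/PaCO2 degrade to criterion-not-met, not an error
  r4 <- list(temp = 38.5, hr = 95, rr = 25)
  expect_identical(attr(screen_sirs(r4, TRUE, th), "criteria"), 3L)
  # missing required vitals do error
  expect_error(screen_sirs(list(temp = 38, hr = 95), TRUE, th),
               class = "dtr_missing_data_error")
})

test_that("fluid dichotomization puts 40 ml/kg/day on the liberal side", {
  expect_identical(dichotomize_fluid(c(40, 39.999, 38.88, 71.52, 0)),
                   c(1L, 0L, 0L, 1L, 0L))
  expect_error(dichotomize_fluid(-1), class = "dtr_invalid_error")
  expect_error(dichotomize_fluid(NA_real_), class = "dtr_invalid_error")
})

test_that("stage records carve outcome times at the day-3 and day-5 boundaries", {
  sr <- stage_records(toy_cohort())
  a <- sr[sr$patient_id == "A", ]
  expect_identical(nrow(a), 1L)
  expect_equal(a$T, 1.5)
  expect_identical(a$event, 1L)
  expect_identical(a$a, 1L)  # 45 ml/kg on day 1

  b <- sr[sr$patient_id == "B", ]
  expect_identical(b$stage, 1:3)
  expect_equal(b$T, c(2, 2, 0.2))
  expect_identical(b$event, c(0L, 0L, 1L))
  expect_identical(b$censored, c(0L, 0L, 0L))
  # decision-day treatments: day 1 (38.88 -> restricted), day 3
  # (39.999 -> restricted), day 5 (10 -> restricted)
  expect_identical(b$a, c(0L, 0L, 0L))

  cc <- sr[sr$patient_id == "C", ]
  expect_equal(cc$T, c(2, 2, 2))
  expect_identical(cc$event, c(0L, 0L, 0L))
  expect_identical(cc$censored, c(0L, 0L, 1L))
  expect_identical(cc$death, c(0L, 0L, 0L))
})

test_that("stage times reconstruct the observed outcome time exactly", {
  coh <- simulate_cohort(sim_params(), 300, seed = 5)
  sr <- stage_records(coh)
  first <- !duplicated(coh$patient_id)
  outc <- ifelse(coh$status[first] == "died", coh$death_time[first],
                 coh$discharge_time[first])
  names(outc) <- coh$patient_id[first]
  tot <- tapply(sr$T, sr$patient_id, sum)
  expect_equal(as.vector(tot[names(outc)]), unname(outc), tolerance = 1e-12)
  # monotone attrition
  n_by_stage <- table(sr$stage)
  expect_true(all(diff(as.integer(n_by_stage)) <= 0))
  # each stage: exactly one of event / censored / survived-to-boundary
  expect_true(all(sr$event + sr$censored <= 1))
})

test_that("malformed trajectories are rejected", {
  coh <- toy_cohort()
  bad <- coh
  bad$death_time[bad$patient_id == "A"] <- -1
  expect_error(stage_records(bad), class = "dtr_malformed_error")
})

test_that("feature assembly applies per-term transforms and history lookups", {
  coh <- toy_cohort()
  spec <- model_spec(1, blip = list(
    term_spec("MBP1", "mbp", 1, "scale", scale = 20),
    term_spec("MBP1sq", "mbp", 1, "scalesq", scale = 20)
  ))
  f <- assemble_features(coh, 1, spec, ids = "A")
  x <- term_matrix(spec$blip, f)
  expect_equal(unname(x[, "MBP1"]), 2.5)    # mBP 50 / 20
  expect_equal(unname(x[, "MBP1sq"]), 6.25)
  spec3 <- model_spec(3, blip = list(
    term_spec("Fluid3", "fluid", 3, "identity"),
    term_spec("Fluid4", "fluid", 4, "identity"),
    term_spec("Fluid34", "fluid", 4, "product", parents = c("Fluid3", "Fluid4"))
  ))
  f3 <- assemble_features(coh, 3, spec3, ids = c("B", "C"))
  x3 <- term_matrix(spec3$blip, f3)
  # B: day-3 39.999 restricted, day-4 40 liberal; C: day-3 41 liberal,
  # day-4 39 restricted -> interaction 0 for both
  expect_equal(unname(x3[, "Fluid34"]), c(0, 0))
  expect_equal(unname(x3[, "Fluid4"]), c(1, 0))
  # two liberal days multiply to 1
  coh2 <- coh
  coh2$fluid_ml_per_kg[coh2$patient_id == "B" & coh2$day == 3] <- 60
  x3b <- term_matrix(spec3$blip, assemble_features(coh2, 3, spec3, ids = "B"))
  expect_equal(unname(x3b[, "Fluid34"]), 1)
  # empty spec -> just the id column
  empty <- assemble_features(coh, 1, model_spec(1, blip = list()), ids = "A")
  expect_identical(names(empty), "patient_id")
  # missing covariate errors with context
  expect_error(
    assemble_features(coh, 3, model_spec(3, blip = list(
      term_spec("Lactate", "lactate", 5, "identity"))), ids = "B"),
    class = "dtr_missing_data_error")
})
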