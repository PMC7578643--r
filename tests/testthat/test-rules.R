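# Frozen oracle values: plain spreadsheet-style arithmetic over the printed
# equation coefficients, computed independently of the package's term
# machinery.
probe_features <- list(
  p1 = list(age = 70, icu_type = "MICU", hr = 120, mbp = 50, mv = 1),
  p2 = list(age = 70, icu_type = "MICU", hr = 120, mbp = 90, mv = 1),
  p3 = list(age = 55, icu_type = "Neuro ICU", hr = 80, mbp = 65, mv = 0),
  p4 = list(age = 80, icu_type = "CCU-CTICU", hr = 100, mbp = 62.1, mv = 0),
  p5 = list(temp = 37, mbp = 60, urine_2 = 1500, urine_1 = 500, mv = 1,
            fluid_2 = 1, fluid_1 = 0),
  p6 = list(mv = 1, hr = 100, mbp = 70, fluid_3 = 1, fluid_4 = 1),
  p7 = list(mv = 0, hr = 90, mbp = 80, fluid_3 = 0, fluid_4 = 1)
)
probe_stage <- c(1, 1, 1, 1, 2, 3, 3)
probe_scores <- c(p1 = 0.011425, p2 = -0.168375, p3 = 1.30613125,
                  p4 = -0.2581357475, p5 = 0.4479,
                  p6 = 0.2246, p7 = -0.1246)

test_that("reference rule blip scores match the arithmetic oracle", {
  reg <- reference_rules()
  for (i in seq_along(probe_features)) {
    s <- blip_score(reg$stages[[probe_stage[i]]], probe_features[[i]])
    expect_equal(s, unname(probe_scores[i]), tolerance = 1e-9,
                 label = names(probe_features)[i])
  }
})

test_that("recommend follows the strict positive-score rule", {
  reg <- reference_rules()
  for (i in seq_along(probe_features)) {
    act <- recommend(reg$stages[[probe_stage[i]]], probe_features[[i]])
    expect_identical(as.character(act),
                     if (probe_scores[i] > 0) "liberal" else "restricted",
                     label = names(probe_features)[i])
  }
  # score exactly zero -> restricted
  r0 <- decision_rule(1, list(term_spec("X", "mbp", 1, "identity")),
                      coef = c(`(Intercept)` = 0, X = 0))
  expect_identical(as.character(recommend(r0, list(mbp = 80))), "restricted")
})

test_that("quadratic vertex of the day-1 rule sits at 62.1 mmHg", {
  reg <- reference_rules()
  v <- quadratic_vertex(reg$stages[[1]], "mbp")
  expect_equal(v, 62.1, tolerance = 0.05 / 62.1)
  # exact arithmetic: 20 * b / (2|c|)
  expect_equal(v, 20 * 0.7074 / (2 * 0.1139), tolerance = 1e-12)
  # day-3 rule has no quadratic mBP term
  expect_error(quadratic_vertex(reg$stages[[2]], "mbp"),
               class = "dtr_novertex_error")
  # zero linear coefficient gives vertex 0
  rq <- decision_rule(1, list(
    term_spec("M", "mbp", 1, "scale", scale = 20),
    term_spec("M2", "mbp", 1, "scalesq", scale = 20)),
    coef = c(`(Intercept)` = 1, M = 0, M2 = -0.2))
  expect_equal(quadratic_vertex(rq, "mbp"), 0)
  # a convex (nonnegative) squared term is rejected
  rc <- decision_rule(1, list(
    term_spec("M", "mbp", 1, "scale", scale = 20),
    term_spec("M2", "mbp", 1, "scalesq", scale = 20)),
    coef = c(`(Intercept)` = 1, M = 0.5, M2 = 0.2))
  expect_error(quadratic_vertex(rc, "mbp"), class = "dtr_novertex_error")
})

test_that("equation coefficients agree with their tabulated 3-decimal values", {
  reg <- reference_rules()
  tol <- 5e-4 * (1 + 1e-9)
  tab1 <- c(`(Intercept)` = -1.248, CSICU = 0.413, CTICU = 0.078,
            CardiacICU = 0.215, MICU = -0.198, MedSurgICU = -0.074,
            NeuroICU = 1.485, SICU = 0.44, HR1 = 0.085, MBP1 = 0.707,
            MBP1sq = -0.114, MV1 = 0.357)
  eq1 <- reg$stages[[1]]$coef
  expect_true(all(abs(eq1[names(tab1)] - tab1) <= tol))
  # age is tabulated per 10-year increase
  expect_lte(abs(10 * eq1[["Age"]] - (-0.067)), tol)
  tab2 <- c(`(Intercept)` = 0.116, Temp3 = -0.004, MBP3 = -0.163,
            Urine2 = 0.175, Urine1 = 0.019, MV3 = 0.534, Fluid2 = 0.151,
            Fluid1 = 0.241)
  expect_true(all(abs(reg$stages[[2]]$coef[names(tab2)] - tab2) <= tol))
  tab3 <- c(`(Intercept)` = -0.557, MV5 = 0.656, HR5 = 0.002, MBP5 = -0.002,
            Fluid3 = 0.115, Fluid4 = 0.432, Fluid34 = -0.457)
  expect_true(all(abs(reg$stages[[3]]$coef[names(tab3)] - tab3) <= tol))
})

test_that("scores are linear in non-squared features and scale-invariant in sign", {
  reg <- reference_rules()
  r1 <- reg$stages[[1]]
  base <- probe_features$p1
  s0 <- blip_score(r1, base)
  shifted <- base; shifted$hr <- base$hr + 15
  expect_equal(blip_score(r1, shifted) - s0, 0.0853 * 15 / 20,
               tolerance = 1e-12)
  # joint positive rescaling never changes the recommendation
  r_scaled <- decision_rule(1, r1$terms, coef = r1$coef * 3.7)
  for (f in probe_features[probe_stage == 1]) {
    expect_identical(as.character(recommend(r_scaled, f)),
                     as.character(recommend(r1, f)))
  }
})

test_that("day-1 score rises below the mBP vertex and falls above it", {
  r1 <- reference_rules()$stages[[1]]
  v <- quadratic_vertex(r1, "mbp")
  grid <- seq(30, 110, by = 2)
  s <- vapply(grid, function(m) {
    f <- probe_features$p1; f$mbp <- m; blip_score(r1, f)
  }, numeric(1))
  below <- grid[-length(grid)] < v & grid[-1] <= v
  above <- grid[-length(grid)] >= v
  expect_true(all(diff(s)[below] > 0))
  expect_true(all(diff(s)[above] < 0))
})

test_that("a regime survives JSON serialization bit-for-bit", {
  reg <- reference_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_regime(reg, path)
  reg2 <- read_regime(path)
  for (k in 1:3) {
    expect_identical(reg2$stages[[k]]$coef, reg$stages[[k]]$coef)
  }
  for (i in seq_along(probe_features)) {
    expect_identical(
      blip_score(reg2$stages[[probe_stage[i]]], probe_features[[i]]),
      blip_score(reg$stages[[probe_stage[i]]], probe_features[[i]]))
  }
})
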