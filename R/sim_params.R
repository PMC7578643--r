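#' Simulation parameters for synthetic ICU cohorts
#'
#' Returns the full parameter set of the synthetic-cohort generator:
#' baseline distributions (age, unit type), first-order autoregressive daily
#' covariate dynamics, persistence models for mechanical ventilation and
#' vasopressor use, the stochastic behaviour policy assigning the daily
#' liberal/restricted fluid strategy, the true stage-wise outcome models
#' (treatment-free coefficients `beta_star`, blip coefficients `psi_star`,
#' log-scale noise `sigma`), and the alive-discharge censoring hazard.
#'
#' Defaults describe a generic septic ICU population: vitals centred at
#' HR 109 bpm, mBP 57 mmHg, RR 29 /min, temperature 37.3 degC, urine
#' 800 ml/day; a behaviour policy whose day-1 marginal liberal-fluid rate is
#' approximately 50%; a day-1 blip that is concave in mBP (negative
#' coefficient on the squared term) and a day-5 blip with a negative
#' interaction between the day-3 and day-4 fluid strategies. Any element can
#' be overridden via `...` (top-level names only).
#'
#' @param ... Named overrides merged over the defaults with
#'   [utils::modifyList()], e.g. `sigma = c(0, 0, 0)` or
#'   `policy = list(mbp = 0, mv = 0)`.
#' @return An object of class `dtr_sim_params`.
#' @seealso [simulate_cohort()]
#' @export
sim_params <- function(...) {
  specs <- default_specs()
  p <- list(
    baseline = list(
      age_mean = 66, age_sd = 15, age_min = 18, age_max = 100,
      icu_levels = icu_levels(),
      icu_probs = c(0.06, 0.02, 0.01, 0.06, 0.13, 0.66, 0.02, 0.04)
    ),
    dynamics = list(
      hr    = list(mean = 109,  between_sd = 15,  within_sd = 10,  rho = 0.7, min = 30),
      mbp   = list(mean = 57,   between_sd = 10,  within_sd = 8,   rho = 0.7, min = 20),
      rr    = list(mean = 29,   between_sd = 5,   within_sd = 4,   rho = 0.7, min = 5),
      temp  = list(mean = 37.3, between_sd = 0.5, within_sd = 0.4, rho = 0.7, min = 34),
      urine = list(mean = 800,  between_sd = 400, within_sd = 300, rho = 0.7, min = 0),
      mv    = list(p1 = 0.24, stay = 0.85, onset = 0.08),
      vasopressor = list(p1 = 0.30, stay = 0.70, onset = 0.15),
      paco2 = list(mean = 38, sd = 6),
      wbc   = list(meanlog = log(11000), sdlog = 0.4),
      band_pct = list(shape = 1, scale = 5, max = 40)
    ),
    # Daily behaviour policy: logit P(liberal) on standardized mBP and MV.
    policy = list(intercept = -0.12, mbp = -0.5, mv = 0.5),
    fluid_volume = list(
      liberal = list(shape = 1.5, scale = 20),   # 40 + gamma, ml/kg/day
      restricted = list(shape1 = 2, shape2 = 1.5) # 40 * beta
    ),
    specs = specs,
    psi_star = list(
      c(`(Intercept)` = -1.9, Age = -0.007, CSICU = 0.45, CTICU = 0.10,
        CardiacICU = 0.25, MICU = -0.25, MedSurgICU = -0.10, NeuroICU = 1.50,
        SICU = 0.45, HR1 = 0.10, MBP1 = 0.90, MBP1sq = -0.16, MV1 = 0.50),
      c(`(Intercept)` = 0.5, Temp3 = -0.004, MBP3 = -0.39, Urine2 = 0.585,
        Urine1 = 0.065, MV3 = 1.04, Fluid2 = 0.325, Fluid1 = 0.455),
      c(`(Intercept)` = -0.6, MV5 = 0.90, Fluid3 = 0.10, Fluid4 = 0.50,
        Fluid34 = -0.45)
    ),
    beta_star = list(
      c(`(Intercept)` = 1.4, Age = -0.002, CSICU = 0, CTICU = 0,
        CardiacICU = 0, MICU = -0.10, MedSurgICU = 0, NeuroICU = 0,
        SICU = 0, HR1 = -0.05, MBP1 = 0.10, MBP1sq = -0.02, MV1 = -0.40),
      c(`(Intercept)` = 0.5, Temp3 = -0.005, MBP3 = 0.10, Urine2 = 0.10,
        Urine1 = 0, MV3 = -0.30, Fluid2 = 0, Fluid1 = 0),
      c(`(Intercept)` = 0.7, MV5 = -0.30, HR5 = -0.002, MBP5 = 0.004,
        Fluid3 = 0, Fluid4 = 0, Fluid34 = 0)
    ),
    sigma = c(0.4, 0.4, 0.25),
    discharge_rate = 0.05,  # exponential alive-discharge hazard, per day
    horizon = 7L            # days of daily records generated
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop_invalid("overrides passed to sim_params() must be named")
    }
    # list-of-vectors fields are replaced outright (modifyList would skip
    # their unnamed elements)
    whole <- intersect(names(over), c("psi_star", "beta_star", "sigma", "specs"))
    for (nm in whole) p[[nm]] <- over[[nm]]
    rest <- over[setdiff(names(over), whole)]
    if (length(rest)) p <- utils::modifyList(p, rest)
  }
  validate_sim_params(p)
  structure(p, class = "dtr_sim_params")
}

validate_sim_params <- function(p) {
  if (any(p$sigma < 0)) stop_invalid("sigma must be nonnegative")
  if (p$discharge_rate < 0) stop_invalid("discharge_rate must be nonnegative")
  pr <- p$baseline$icu_probs
  if (length(pr) != length(p$baseline$icu_levels) ||
      abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
    stop_invalid("icu_probs must be nonnegative and sum to 1")
  }
  for (v in c("hr", "mbp", "rr", "temp", "urine")) {
    d <- p$dynamics[[v]]
    if (d$between_sd <= 0 || d$within_sd <= 0) {
      stop_invalid(sprintf("dynamics for '%s': SDs must be strictly positive", v))
    }
    if (abs(d$rho) >= 1) stop_invalid(sprintf("dynamics for '%s': |rho| < 1 required", v))
  }
  for (v in c("mv", "vasopressor")) {
    d <- p$dynamics[[v]]
    if (any(unlist(d) <= 0) || any(unlist(d) >= 1)) {
      stop_invalid(sprintf("dynamics for '%s': probabilities must lie in (0,1)", v))
    }
  }
  for (k in 1:3) {
    want <- c("(Intercept)", term_names(p$specs[[k]]$blip))
    if (!identical(names(p$psi_star[[k]]), want)) {
      stop_invalid(sprintf("psi_star[[%d]] names must match the stage-%d blip terms", k, k))
    }
    want_tf <- c("(Intercept)", term_names(p$specs[[k]]$treatment_free))
    if (!identical(names(p$beta_star[[k]]), want_tf)) {
      stop_invalid(sprintf("beta_star[[%d]] names must match the stage-%d treatment-free terms", k, k))
    }
  }
  invisible(p)
}

#' @export
print.dtr_sim_params <- function(x, ...) {
  cat("Synthetic ICU cohort parameters\n")
  cat(sprintf("  horizon: %d days; discharge hazard: %.3f /day; sigma: %s\n",
              x$horizon, x$discharge_rate,
              paste(format(x$sigma), collapse = ", ")))
  cat(sprintf("  policy logit: %.2f %+.2f*(mBP-57)/12 %+.2f*MV\n",
              x$policy$intercept, x$policy$mbp, x$policy$mv))
  for (k in 1:3) {
    cat(sprintf("  stage %d psi*: %s\n", k,
                paste(sprintf("%s=%.3g", names(x$psi_star[[k]]),
                              x$psi_star[[k]]), collapse = " ")))
  }
  invisible(x)
}
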