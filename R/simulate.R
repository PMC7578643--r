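#' Simulate a synthetic ICU cohort
#'
#' Generates `n` patient trajectories with the statistical structure the DTR
#' analysis assumes: baseline age and unit type; first-order autoregressive
#' daily vitals over `params$horizon` days; persistent mechanical-ventilation
#' and vasopressor states; a stochastic behaviour policy assigning the daily
#' liberal/restricted fluid strategy from current mBP and ventilation; and
#' stage-wise survival times drawn from accelerated failure time models
#' \deqn{\log T_k = \beta_k^{*T} h_{k\beta} + a_k \psi_k^{*T} h_{k\psi} + \epsilon_k,
#'   \quad \epsilon_k \sim N(0, \sigma_k^2),}
#' where death occurs in stage k if the drawn time is shorter than the
#' two-day stage span (stage 3 is open-ended). Alive discharge is an
#' independent exponential clock truncated to occur after day 1. Stage death
#' times are drawn continuously with a floor of 0.04 days so the log is
#' always defined. Identical `(params, n, seed)` give identical output; the
#' caller's RNG state is left untouched.
#'
#' @param params A [sim_params()] object.
#' @param n Number of patients (nonnegative integer).
#' @param seed Integer seed.
#' @return Data frame of class `dtr_cohort`, one row per patient-day, sorted
#'   by `(patient_id, day)`, with daily records up to
#'   `ceiling(min(outcome time, horizon))`.
#' @examples
#' coh <- simulate_cohort(sim_params(), n = 50, seed = 1)
#' table(coh$status[!duplicated(coh$patient_id)])
#' @export
simulate_cohort <- function(params = sim_params(), n, seed) {
  if (!inherits(params, "dtr_sim_params")) {
    stop_invalid("`params` must come from sim_params()")
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop_invalid("`n` must be a nonnegative integer")
  }
  n <- as.integer(n)
  if (n == 0L) return(empty_cohort())
  with_seed(seed, simulate_cohort_impl(params, n))
}

empty_cohort <- function() {
  cols <- cohort_columns()
  out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  class(out) <- c("dtr_cohort", "data.frame")
  out
}

cohort_columns <- function() {
  c("patient_id", "day", "age", "icu_type", "hr", "mbp", "rr", "temp",
    "urine_ml", "mv", "vasopressor", "fluid_ml_per_kg",
    "death_time", "discharge_time", "status", "paco2", "wbc", "band_pct")
}

simulate_cohort_impl <- function(params, n) {
  H <- params$horizon
  dyn <- params$dynamics
  bl <- params$baseline

  age <- as.integer(pmin(pmax(round(stats::rnorm(n, bl$age_mean, bl$age_sd)),
                              bl$age_min), bl$age_max))
  icu <- sample(bl$icu_levels, n, replace = TRUE, prob = bl$icu_probs)

  ar_path <- function(d) {
    m <- stats::rnorm(n, d$mean, d$between_sd)
    x <- matrix(NA_real_, n, H)
    x[, 1] <- m + stats::rnorm(n, 0, d$within_sd)
    innov_sd <- d$within_sd * sqrt(1 - d$rho^2)
    for (j in 2:H) {
      x[, j] <- m + d$rho * (x[, j - 1] - m) + stats::rnorm(n, 0, innov_sd)
    }
    pmax(x, d$min)
  }
  hr <- ar_path(dyn$hr); mbp <- ar_path(dyn$mbp); rr <- ar_path(dyn$rr)
  temp <- ar_path(dyn$temp); urine <- ar_path(dyn$urine)

  markov_path <- function(d) {
    x <- matrix(0L, n, H)
    x[, 1] <- stats::rbinom(n, 1, d$p1)
    for (j in 2:H) {
      p <- ifelse(x[, j - 1] == 1L, d$stay, d$onset)
      x[, j] <- stats::rbinom(n, 1, p)
    }
    x
  }
  mv <- markov_path(dyn$mv)
  vaso <- markov_path(dyn$vasopressor)

  paco2 <- matrix(stats::rnorm(n * H, dyn$paco2$mean, dyn$paco2$sd), n, H)
  wbc <- matrix(stats::rlnorm(n * H, dyn$wbc$meanlog, dyn$wbc$sdlog), n, H)
  band <- matrix(pmin(stats::rgamma(n * H, dyn$band_pct$shape,
                                    scale = dyn$band_pct$scale),
                      dyn$band_pct$max), n, H)

  # Behaviour policy and fluid volumes, day by day.
  pol <- params$policy
  lf <- matrix(0L, n, H)
  vol <- matrix(NA_real_, n, H)
  fv <- params$fluid_volume
  for (j in seq_len(H)) {
    eta <- pol$intercept + pol$mbp * (mbp[, j] - 57) / 12 + pol$mv * mv[, j]
    lf[, j] <- stats::rbinom(n, 1, stats::plogis(eta))
    v_lib <- 40 + stats::rgamma(n, shape = fv$liberal$shape,
                                scale = fv$liberal$scale)
    v_res <- 40 * stats::rbeta(n, fv$restricted$shape1, fv$restricted$shape2)
    vol[, j] <- ifelse(lf[, j] == 1L, v_lib, v_res)
  }

  pid <- sprintf("P%05d", seq_len(n))
  full <- data.frame(
    patient_id = rep(pid, each = H),
    day = rep(seq_len(H), times = n),
    age = rep(age, each = H),
    icu_type = rep(icu, each = H),
    hr = as.vector(t(hr)), mbp = as.vector(t(mbp)), rr = as.vector(t(rr)),
    temp = as.vector(t(temp)), urine_ml = as.vector(t(urine)),
    mv = as.vector(t(mv)), vasopressor = as.vector(t(vaso)),
    fluid_ml_per_kg = as.vector(t(vol)),
    death_time = NA_real_, discharge_time = NA_real_,
    status = NA_character_,
    paco2 = as.vector(t(paco2)), wbc = as.vector(t(wbc)),
    band_pct = as.vector(t(band)),
    stringsAsFactors = FALSE
  )

  # Stage-wise survival from the true AFT models, evaluated through the same
  # term machinery the estimator uses.
  eps <- lapply(1:3, function(k) stats::rnorm(n, 0, params$sigma[k]))
  stage_T <- matrix(NA_real_, n, 3)
  a_stage <- cbind(lf[, 1], lf[, 3], lf[, 5])
  for (k in 1:3) {
    spec <- params$specs[[k]]
    feats <- assemble_features(full, k, spec, ids = pid)
    xb <- term_matrix(spec$treatment_free, feats)
    xp <- term_matrix(spec$blip, feats)
    lt <- drop(xb %*% params$beta_star[[k]]) +
      a_stage[, k] * drop(xp %*% params$psi_star[[k]]) + eps[[k]]
    stage_T[, k] <- pmax(exp(lt), 0.04)
  }
  death <- ifelse(stage_T[, 1] < 2, stage_T[, 1],
                  ifelse(stage_T[, 2] < 2, 2 + stage_T[, 2],
                         4 + stage_T[, 3]))
  disch <- if (params$discharge_rate > 0) {
    1 + stats::rexp(n, params$discharge_rate)
  } else rep(Inf, n)
  died <- death <= disch
  outcome <- pmin(death, disch)

  full$death_time <- rep(ifelse(died, death, NA_real_), each = H)
  full$discharge_time <- rep(ifelse(died, NA_real_, disch), each = H)
  full$status <- rep(ifelse(died, "died", "discharged_alive"), each = H)

  keep_days <- pmin(H, ceiling(outcome))
  keep <- full$day <= rep(keep_days, each = H)
  out <- full[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dtr_cohort", "data.frame")
  out
}

#' @export
print.dtr_cohort <- function(x, ...) {
  np <- length(unique(x$patient_id))
  cat(sprintf("Synthetic/loaded ICU cohort: %d patients, %d patient-days\n",
              np, nrow(x)))
  if (np) {
    st <- table(x$status[!duplicated(x$patient_id)])
    cat("  outcomes:", paste(sprintf("%s=%d", names(st), st), collapse = ", "),
        "\n")
    print(utils::head(as.data.frame(x), 4))
    if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  }
  invisible(x)
}
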