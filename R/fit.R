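#' Fit the nuisance models for one stage
#'
#' Fits two logistic regressions on the entered stage records: the treatment
#' model P(a = 1 | h) (propensity of liberal fluid) and the censoring model
#' P(death observed | h), both on the stage's blip covariates. Fitted
#' probabilities are clipped to \[0.01, 0.99\] so the downstream weights stay
#' bounded.
#'
#' @param a Binary treatment vector (1 = liberal).
#' @param delta Binary indicator that the patient's death was observed
#'   (0 = censored by alive discharge).
#' @param x Design matrix including an intercept column (e.g. from
#'   [term_matrix()] on the blip terms).
#' @return Object of class `dtr_nuisance` with elements `propensity`,
#'   `censoring` (coefficients) and fitted probabilities `pi`, `K`.
#' @export
fit_nuisance <- function(a, delta, x) {
  a <- as.integer(a); delta <- as.integer(delta)
  if (length(unique(a)) < 2L) {
    stop_degenerate("all stage records received the same treatment; cannot fit a propensity model")
  }
  if (min(tabulate(a + 1L, 2L)) < 2L) {
    stop_degenerate("need at least 2 records in each treatment arm")
  }
  logit_fit <- function(yy) {
    if (length(unique(yy)) < 2L) {
      # Degenerate outcome (e.g. no censoring): constant probability at the
      # clip bound.
      return(list(coef = NULL, p = clip_prob(rep(mean(yy), length(yy)))))
    }
    f <- suppressWarnings(stats::glm.fit(x, yy, family = stats::binomial()))
    list(coef = stats::setNames(f$coefficients, colnames(x)),
         p = clip_prob(f$fitted.values))
  }
  ft <- logit_fit(a)
  fc <- logit_fit(delta)
  structure(list(propensity = ft$coef, censoring = fc$coef,
                 pi = ft$p, K = fc$p),
            class = "dtr_nuisance")
}

#' Doubly-weighted estimation weights
#'
#' The per-record weight is the balancing weight |a - pi(h)| times the
#' inverse-probability-of-censoring factor delta / K(h). Records censored by
#' alive discharge (delta = 0) receive weight zero; observed deaths are
#' reweighted by the inverse fitted probability of being uncensored.
#'
#' @param nuisance A [fit_nuisance()] object (fitted on the same records, in
#'   the same order).
#' @param a Binary treatment vector.
#' @param delta Binary observed-death indicator.
#' @return Nonnegative numeric weight vector.
#' @export
compute_weights <- function(nuisance, a, delta) {
  if (!inherits(nuisance, "dtr_nuisance")) {
    stop_invalid("`nuisance` must come from fit_nuisance()")
  }
  abs(as.numeric(a) - nuisance$pi) * (as.numeric(delta) / nuisance$K)
}

#' Weighted least-squares blip fit for one stage
#'
#' Regresses log survival time (possibly already adjusted for optimal later
#' treatment) on the concatenated design \[treatment-free terms | a x blip
#' terms\] by weighted least squares, returning the blip coefficients psi,
#' the treatment-free coefficients beta, sandwich-type standard errors, 95%
#' confidence bounds and Wald p-values.
#'
#' @param y Log survival outcome (finite; strictly positive times).
#' @param a Binary treatment.
#' @param x_blip Blip design matrix with intercept (from [term_matrix()]).
#' @param x_tf Treatment-free design matrix with intercept.
#' @param weights Nonnegative weights (see [compute_weights()]); both arms
#'   must carry positive total weight.
#' @param on_alias Behaviour when the design is rank deficient: `"error"`
#'   (default) raises a collinearity error listing the aliased terms;
#'   `"drop"` silently removes the aliased columns and refits (used inside
#'   bootstrap replicates, where a rare indicator level can vanish from a
#'   resample).
#' @return Object of class `dtr_blip_fit` with elements `psi`, `beta`,
#'   `se_psi`, `se_beta`, `ci_psi` (2-column matrix), `p_psi`, `p_beta`,
#'   `n_used`, `sigma2`.
#' @export
fit_stage_blip <- function(y, a, x_blip, x_tf, weights,
                           on_alias = c("error", "drop")) {
  on_alias <- match.arg(on_alias)
  a <- as.numeric(a)
  if (any(!is.finite(y))) stop_invalid("outcome log-times must be finite (times strictly positive)")
  if (any(weights < 0)) stop_invalid("weights must be nonnegative")
  if (sum(weights[a == 1]) <= 0 || sum(weights[a == 0]) <= 0) {
    stop_degenerate("positive total weight required in both treatment arms")
  }
  X <- cbind(x_tf, x_blip * a)
  colnames(X) <- c(paste0("tf:", colnames(x_tf)),
                   paste0("blip:", colnames(x_blip)))
  fit <- stats::lm.wfit(X, y, weights)
  if (anyNA(fit$coefficients)) {
    bad <- names(fit$coefficients)[is.na(fit$coefficients)]
    if (on_alias == "error") {
      stop_collinear(paste("rank-deficient design; aliased terms:",
                           paste(bad, collapse = ", ")))
    }
    keep_tf <- setdiff(colnames(x_tf),
                       sub("^tf:", "", grep("^tf:", bad, value = TRUE)))
    keep_bl <- setdiff(colnames(x_blip),
                       sub("^blip:", "", grep("^blip:", bad, value = TRUE)))
    return(fit_stage_blip(y, a, x_blip[, keep_bl, drop = FALSE],
                          x_tf[, keep_tf, drop = FALSE], weights,
                          on_alias = "drop"))
  }
  p_tf <- ncol(x_tf); p_bl <- ncol(x_blip)
  b <- fit$coefficients
  r <- y - drop(X %*% b)
  A <- crossprod(X, X * weights)
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop_collinear("weighted normal equations are singular")
  })
  Z <- X * (weights * r)
  V <- Ainv %*% crossprod(Z) %*% Ainv
  se <- sqrt(pmax(diag(V), 0))
  pval <- 2 * stats::pnorm(-abs(b / ifelse(se > 0, se, Inf)))
  z <- stats::qnorm(0.975)
  idx_bl <- p_tf + seq_len(p_bl)
  psi <- stats::setNames(b[idx_bl], colnames(x_blip))
  beta <- stats::setNames(b[seq_len(p_tf)], colnames(x_tf))
  structure(list(
    psi = psi, beta = beta,
    se_psi = stats::setNames(se[idx_bl], names(psi)),
    se_beta = stats::setNames(se[seq_len(p_tf)], names(beta)),
    ci_psi = cbind(lower = psi - z * se[idx_bl], upper = psi + z * se[idx_bl]),
    p_psi = stats::setNames(pval[idx_bl], names(psi)),
    p_beta = stats::setNames(pval[seq_len(p_tf)], names(beta)),
    vcov = V, n_used = sum(weights > 0),
    sigma2 = sum(weights * r^2) / max(sum(weights), .Machine$double.eps)
  ), class = "dtr_blip_fit")
}

#' @export
print.dtr_blip_fit <- function(x, ...) {
  cat(sprintf("Stage blip fit (%d weighted records)\n", x$n_used))
  tab <- data.frame(estimate = x$psi, se = x$se_psi,
                    lower = x$ci_psi[, 1], upper = x$ci_psi[, 2],
                    p = x$p_psi)
  print(round(tab, 4))
  invisible(x)
}

#' Backward elimination of blip terms
#'
#' Iteratively removes the least significant non-forced blip term with Wald
#' p-value above `alpha`, refitting after each removal, until every remaining
#' non-forced term is significant. The intercept and `forced` terms are never
#' removed. The treatment-free design is left untouched.
#'
#' @inheritParams fit_stage_blip
#' @param forced Names of blip columns that must be retained (the intercept
#'   is always retained).
#' @param alpha Significance threshold.
#' @return List with the final `fit`, the retained blip column names `kept`,
#'   and the removed names `dropped`.
#' @export
select_variables <- function(y, a, x_blip, x_tf, weights,
                             forced = character(), alpha = 0.05) {
  keep <- colnames(x_blip)
  dropped <- character()
  protected <- union("(Intercept)", forced)
  repeat {
    fit <- fit_stage_blip(y, a, x_blip[, keep, drop = FALSE], x_tf, weights)
    cand <- setdiff(keep, protected)
    if (!length(cand)) break
    p <- fit$p_psi[cand]
    if (max(p) <= alpha) break
    worst <- cand[which.max(p)]
    keep <- setdiff(keep, worst)
    dropped <- c(dropped, worst)
  }
  list(fit = fit, kept = keep, dropped = dropped)
}

#' Counterfactual survival-time adjustment
#'
#' Inflates the current-stage portion of the remaining survival time to its
#' value under the optimal current-stage treatment:
#' \deqn{\tilde T = T_{earlier} + T_{current} \exp\{\psi^T h_\psi (a^{opt} - a)\}.}
#' The result equals the observed remaining time when `a == a_opt`, and is
#' never smaller than it when `a_opt` is the indicator of a positive blip
#' score.
#'
#' @param t_earlier Earlier-stage portion of the remaining time (days, >= 0).
#' @param t_current Current-stage portion (days, > 0).
#' @param blip_score Blip score psi' h for the record.
#' @param a Received treatment (0/1).
#' @param a_opt Optimal treatment (0/1).
#' @return Adjusted remaining time in days (vectorized).
#' @export
adjust_counterfactual <- function(t_earlier, t_current, blip_score, a, a_opt) {
  if (any(t_current <= 0) || any(t_earlier < 0)) {
    stop_invalid("times must be positive (earlier portion nonnegative)")
  }
  t_earlier + t_current * exp(blip_score * (as.numeric(a_opt) - as.numeric(a)))
}

# --- backward induction core ----------------------------------------------

# `stages` is a list of up to three entries, each NULL or a list with
# elements inst (unique instance ids; stage k+1 instances are a subset of
# stage k), a, delta, T, Xpsi, Xbeta, forced. Instances let the bootstrap
# resample whole patients (possibly repeatedly) without id collisions.
induct_core <- function(stages, select = FALSE, alpha = 0.05,
                        on_alias = "error") {
  out <- vector("list", 3L)
  adj_inst <- NULL; adj_val <- NULL
  for (k in 3:1) {
    s <- stages[[k]]
    if (is.null(s) || !length(s$a)) next
    nxt <- numeric(length(s$a))
    if (length(adj_inst)) {
      m <- match(adj_inst, s$inst)
      if (anyNA(m)) stop_invalid("internal: later-stage instances missing at earlier stage")
      nxt[m] <- adj_val
    }
    t_plus <- s$T + nxt
    step <- tryCatch({
      y <- log(t_plus)
      nuis <- fit_nuisance(s$a, s$delta, s$Xpsi)
      w <- compute_weights(nuis, s$a, s$delta)
      if (select) {
        sel <- select_variables(y, s$a, s$Xpsi, s$Xbeta, w,
                                forced = s$forced, alpha = alpha)
        fit <- sel$fit; kept <- sel$kept; dropped <- sel$dropped
      } else {
        fit <- fit_stage_blip(y, s$a, s$Xpsi, s$Xbeta, w,
                              on_alias = on_alias)
        kept <- names(fit$psi); dropped <- character()
      }
      blip <- drop(s$Xpsi[, names(fit$psi), drop = FALSE] %*% fit$psi)
      a_opt <- as.integer(blip > 0)
      t_tilde <- adjust_counterfactual(0, t_plus, blip, s$a, a_opt)
      list(fit = fit, nuisance = nuis, weights = w, blip = blip,
           a_opt = a_opt, t_tilde = t_tilde, t_plus = t_plus,
           kept = kept, dropped = dropped)
    }, dtr_error = function(e) {
      dtr_error(sprintf("stage %d: %s", k, conditionMessage(e)),
                class(e)[1])
    })
    adj_inst <- s$inst; adj_val <- step$t_tilde
    out[[k]] <- step
  }
  out
}

build_stages <- function(cohort, records, specs) {
  lapply(1:3, function(k) {
    rec <- records[records$stage == k, , drop = FALSE]
    if (!nrow(rec)) return(NULL)
    spec <- specs[[k]]
    feats <- assemble_features(cohort, k, spec, ids = rec$patient_id)
    blip_terms <- spec$blip
    forced <- term_names(blip_terms)[vapply(blip_terms, `[[`, logical(1), "forced")]
    list(inst = rec$patient_id, a = rec$a, delta = rec$death, T = rec$T,
         Xpsi = term_matrix(blip_terms, feats),
         Xbeta = term_matrix(spec$treatment_free, feats),
         forced = forced, terms = blip_terms, records = rec)
  })
}

#' Fit a three-stage dynamic treatment regimen
#'
#' Estimates the optimal fluid-management regime by backward induction. For
#' each stage, starting from the last: a logistic propensity and a logistic
#' censoring model are fitted on the blip covariates; records are weighted by
#' |a - pi| x delta / K (balancing times inverse-probability-of-censoring
#' weights); log remaining survival time -- with later stages already
#' adjusted to their optimal treatment -- is regressed on the treatment-free
#' and treatment-interacted blip terms by weighted least squares; the optimal
#' action is the indicator of a positive blip score; and the remaining time
#' is counterfactually inflated before being passed to the next-earlier
#' stage. Stages with no entered patients are skipped.
#'
#' @param cohort Cohort data frame ([simulate_cohort()] / [read_cohort()]).
#' @param specs List of three [model_spec()] objects; defaults to
#'   [default_specs()].
#' @param select If `TRUE`, backward elimination ([select_variables()]) is
#'   applied to each stage's blip terms before the final fit.
#' @param alpha Significance threshold for selection.
#' @param on_alias Passed to [fit_stage_blip()]: `"error"` (default) or
#'   `"drop"` for pipelines that prefer dropping empty indicator columns
#'   (e.g. a rare unit type with no treated patients in a small cohort).
#' @return Object of class `dtr`: a list with the fitted `rules` (a
#'   `dtr_regime`), per-stage `fits` ([fit_stage_blip()] objects), `nuisance`
#'   models, and `records` -- the stage records annotated with `blip_score`,
#'   `optimal_action` and the adjusted counterfactual remaining time
#'   `t_tilde`.
#' @examples
#' coh <- simulate_cohort(sim_params(), n = 300, seed = 7)
#' fit <- dtr_fit(coh)
#' coef(fit, stage = 3)
#' @export
dtr_fit <- function(cohort, specs = default_specs(), select = FALSE,
                    alpha = 0.05, on_alias = c("error", "drop")) {
  on_alias <- match.arg(on_alias)
  cl <- match.call()
  records <- stage_records(cohort)
  stages <- build_stages(cohort, records, specs)
  res <- induct_core(stages, select = select, alpha = alpha,
                     on_alias = on_alias)
  rules <- vector("list", 3L)
  ann <- list()
  for (k in 1:3) {
    if (is.null(res[[k]])) next
    kept <- names(res[[k]]$fit$psi)
    terms_k <- stages[[k]]$terms
    terms_kept <- terms_k[term_names(terms_k) %in% kept]
    rules[[k]] <- decision_rule(stage = k, terms = terms_kept,
                                coef = res[[k]]$fit$psi)
    rec <- stages[[k]]$records
    rec$blip_score <- res[[k]]$blip
    rec$optimal_action <- res[[k]]$a_opt
    rec$t_tilde <- res[[k]]$t_tilde
    fitted_k <- drop(stages[[k]]$Xbeta %*% res[[k]]$fit$beta) +
      rec$a * rec$blip_score
    rec$residual <- log(res[[k]]$t_plus) - fitted_k
    ann[[k]] <- rec
  }
  ann <- do.call(rbind, ann)
  rownames(ann) <- NULL
  class(ann) <- c("dtr_stage_records", "data.frame")
  structure(list(
    call = cl,
    specs = specs, select = select, alpha = alpha,
    rules = new_regime(rules, provenance = "fitted"),
    fits = lapply(res, function(r) r$fit),
    nuisance = lapply(res, function(r) r$nuisance),
    weights = lapply(res, function(r) r$weights),
    dropped = lapply(res, function(r) r$dropped),
    records = ann,
    n_patients = length(unique(records$patient_id))
  ), class = "dtr")
}

#' Patient-level bootstrap confidence intervals for the blip coefficients
#'
#' Resamples whole patients with replacement, reruns the full backward
#' induction on each replicate, and reports percentile 95% intervals for
#' every stage's blip coefficients. Deterministic given `seed`. Replicates
#' whose fit fails (e.g. a single-arm resample) are skipped; more than 20%
#' failures is an error. Under `select = TRUE` a term dropped in a replicate
#' contributes a coefficient of zero (the rule's score treats absent terms as
#' zero).
#'
#' @inheritParams dtr_fit
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @return Object of class `dtr_boot`: per-stage data frames with columns
#'   `term`, `estimate` (full-sample), `lower`, `upper`, plus `B` and
#'   `n_fail`.
#' @export
dtr_boot <- function(cohort, specs = default_specs(), B = 200, seed,
                     select = FALSE, alpha = 0.05) {
  if (B < 2) stop_invalid("B must be at least 2")
  records <- stage_records(cohort)
  stages <- build_stages(cohort, records, specs)
  full <- induct_core(stages, select = select, alpha = alpha,
                      on_alias = "drop")
  patients <- unique(records$patient_id)
  # Per-stage row lookup for each patient (one row per patient per stage).
  row_of <- lapply(stages, function(s) {
    if (is.null(s)) NULL else stats::setNames(seq_along(s$inst), s$inst)
  })
  draw_names <- lapply(stages, function(s) {
    if (is.null(s)) NULL else colnames(s$Xpsi)
  })
  draws <- lapply(draw_names, function(nm) {
    if (is.null(nm)) NULL else
      matrix(NA_real_, B, length(nm), dimnames = list(NULL, nm))
  })
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      S <- sample(patients, replace = TRUE)
      stages_b <- lapply(1:3, function(k) {
        s <- stages[[k]]
        if (is.null(s)) return(NULL)
        rows <- row_of[[k]][S]
        inst <- which(!is.na(rows))
        rows <- rows[inst]
        if (!length(rows)) return(NULL)
        list(inst = inst, a = s$a[rows], delta = s$delta[rows],
             T = s$T[rows], Xpsi = s$Xpsi[rows, , drop = FALSE],
             Xbeta = s$Xbeta[rows, , drop = FALSE], forced = s$forced)
      })
      res_b <- tryCatch(induct_core(stages_b, select = select, alpha = alpha,
                                    on_alias = "drop"),
                        dtr_error = function(e) NULL)
      if (is.null(res_b)) { n_fail <- n_fail + 1L; next }
      for (k in 1:3) {
        if (is.null(res_b[[k]]) || is.null(draws[[k]])) next
        v <- stats::setNames(numeric(ncol(draws[[k]])), colnames(draws[[k]]))
        v[names(res_b[[k]]$fit$psi)] <- res_b[[k]]$fit$psi
        draws[[k]][b, ] <- v
      }
    }
  })
  if (n_fail > 0.2 * B) {
    stop_degenerate(sprintf("bootstrap: %d of %d replicates failed", n_fail, B))
  }
  tables <- lapply(1:3, function(k) {
    if (is.null(draws[[k]]) || is.null(full[[k]])) return(NULL)
    qs <- apply(draws[[k]], 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, na.rm = TRUE)
    est <- stats::setNames(numeric(ncol(draws[[k]])), colnames(draws[[k]]))
    est[names(full[[k]]$fit$psi)] <- full[[k]]$fit$psi
    data.frame(term = colnames(draws[[k]]), estimate = unname(est),
               lower = qs[1, ], upper = qs[2, ], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  structure(list(stages = tables, B = B, n_fail = n_fail, seed = seed),
            class = "dtr_boot")
}

#' @export
print.dtr_boot <- function(x, ...) {
  cat(sprintf("Patient bootstrap: B = %d (%d failed)\n", x$B, x$n_fail))
  for (k in 1:3) {
    if (is.null(x$stages[[k]])) next
    cat(sprintf("Stage %d blip coefficients (percentile 95%% CI):\n", k))
    tab <- x$stages[[k]]
    tab[, -1] <- round(tab[, -1], 4)
    print(tab)
  }
  invisible(x)
}

# --- methods for class dtr -------------------------------------------------

#' @export
print.dtr <- function(x, ...) {
  cat("Three-stage dynamic treatment regimen fit\n")
  cat(sprintf("  %d patients; stages fitted: %s%s\n", x$n_patients,
              paste(which(!vapply(x$fits, is.null, logical(1))), collapse = ", "),
              if (x$select) " (with backward elimination)" else ""))
  for (k in 1:3) {
    if (is.null(x$fits[[k]])) next
    cat(sprintf("  stage %d blip: %s\n", k,
                paste(sprintf("%s=%.3f", names(x$fits[[k]]$psi),
                              x$fits[[k]]$psi), collapse = " ")))
  }
  invisible(x)
}

#' @export
coef.dtr <- function(object, stage = NULL,
                     component = c("blip", "treatment_free"), ...) {
  component <- match.arg(component)
  pick <- function(k) {
    f <- object$fits[[k]]
    if (is.null(f)) NULL else if (component == "blip") f$psi else f$beta
  }
  if (!is.null(stage)) return(pick(stage))
  stats::setNames(lapply(1:3, pick), paste0("stage", 1:3))
}

#' @export
confint.dtr <- function(object, parm, level = 0.95, stage = NULL, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  one <- function(k) {
    f <- object$fits[[k]]
    if (is.null(f)) return(NULL)
    ci <- cbind(f$psi - z * f$se_psi, f$psi + z * f$se_psi)
    colnames(ci) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
    ci
  }
  if (!is.null(stage)) return(one(stage))
  stats::setNames(lapply(1:3, one), paste0("stage", 1:3))
}

#' @export
summary.dtr <- function(object, ...) {
  tabs <- lapply(1:3, function(k) {
    f <- object$fits[[k]]
    if (is.null(f)) return(NULL)
    data.frame(term = names(f$psi), estimate = unname(f$psi),
               se = unname(f$se_psi), lower = f$ci_psi[, 1],
               upper = f$ci_psi[, 2], p = unname(f$p_psi),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  xt <- lapply(1:3, function(k) {
    rec <- object$records[object$records$stage == k, , drop = FALSE]
    if (!nrow(rec)) return(NULL)
    crosstab(rec)
  })
  structure(list(coefficients = tabs, crosstabs = xt,
                 n_patients = object$n_patients, select = object$select,
                 dropped = object$dropped),
            class = "summary.dtr")
}

#' @export
print.summary.dtr <- function(x, ...) {
  cat("Three-stage dynamic treatment regimen fit\n")
  cat(sprintf("  patients: %d\n", x$n_patients))
  for (k in 1:3) {
    if (is.null(x$coefficients[[k]])) next
    cat(sprintf("\nStage %d blip function:\n", k))
    tab <- x$coefficients[[k]]
    tab[, -1] <- round(tab[, -1], 4)
    print(tab)
    if (x$select && length(x$dropped[[k]])) {
      cat("  dropped terms:", paste(x$dropped[[k]], collapse = ", "), "\n")
    }
  }
  cat("\nOptimal vs received treatment:\n")
  for (k in 1:3) if (!is.null(x$crosstabs[[k]])) print(x$crosstabs[[k]])
  invisible(x)
}

#' @export
predict.dtr <- function(object, newdata = NULL, stage = NULL,
                        type = c("action", "score"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    rec <- object$records
    if (!is.null(stage)) rec <- rec[rec$stage == stage, , drop = FALSE]
    return(if (type == "action") rec$optimal_action else rec$blip_score)
  }
  predict(object$rules, newdata = newdata, stage = stage, type = type, ...)
}

#' @export
residuals.dtr <- function(object, stage = NULL, ...) {
  rec <- object$records
  if (!is.null(stage)) rec <- rec[rec$stage == stage, , drop = FALSE]
  stats::setNames(rec$residual, rec$patient_id)
}

#' @export
plot.dtr <- function(x, stage = 1, ...) {
  rec <- x$records[x$records$stage == stage, , drop = FALSE]
  if (!nrow(rec)) stop_invalid(sprintf("no records for stage %d", stage))
  graphics::hist(rec$blip_score, breaks = 30, col = "grey80",
                 main = sprintf("Stage %d blip scores", stage),
                 xlab = "blip score (log-days benefit of liberal fluid)")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
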