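#' Cross table of received versus optimal treatment
#'
#' Tabulates, for one stage, how many patients actually received the
#' restricted/liberal strategy against what the fitted (or fixed) rule
#' recommends, with each cell also expressed as a percentage of the stage
#' total rounded to one decimal.
#'
#' @param x Either a data frame of annotated stage records for a single
#'   stage (columns `a` and `optimal_action`, as produced by [dtr_fit()]), or
#'   a 2x2 counts matrix with received strategy in rows (restricted,
#'   liberal) and optimal strategy in columns.
#' @param stage Optional stage label carried in the result.
#' @return Object of class `dtr_crosstab`: list with `counts`, `pct`,
#'   `total`, `stage`.
#' @examples
#' crosstab(matrix(c(10728, 4410, 5248, 2455), 2))
#' @export
crosstab <- function(x, stage = NULL) {
  lv <- c("restricted", "liberal")
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    counts <- x
  } else {
    if (is.null(x$a) || is.null(x$optimal_action)) {
      stop_invalid("records must carry both `a` and `optimal_action`")
    }
    if (is.null(stage) && length(unique(x$stage)) == 1L) stage <- x$stage[1]
    counts <- table(factor(x$a, levels = 0:1),
                    factor(x$optimal_action, levels = 0:1))
    counts <- matrix(as.integer(counts), 2L, 2L)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(received = lv, optimal = lv)
  total <- sum(counts)
  pct <- round(100 * counts / total, 1)
  structure(list(counts = counts, pct = pct, total = total, stage = stage),
            class = "dtr_crosstab")
}

#' @export
print.dtr_crosstab <- function(x, ...) {
  hdr <- if (is.null(x$stage)) "Received vs optimal treatment"
         else sprintf("Stage %s: received vs optimal treatment", x$stage)
  cat(hdr, sprintf("(n = %d)\n", x$total))
  show <- matrix(sprintf("%d (%.1f%%)", x$counts, x$pct), 2L, 2L,
                 dimnames = dimnames(x$counts))
  print(show, quote = FALSE)
  invisible(x)
}

#' Survival value of a regime
#'
#' Computes, for every patient, the observed total survival/follow-up time
#' and the counterfactual time had the patient followed the regime's
#' recommendation at every entered stage, composing the counterfactual
#' adjustment from the last entered stage inward:
#' remaining_k = (T_k + remaining_{k+1}) x exp(blip_k x (a_k^rec - a_k)).
#' Because each rule recommends its own positive-blip action, the
#' counterfactual time is never smaller than the observed time.
#'
#' @param cohort Cohort data frame.
#' @param regime A `dtr_regime` (fitted via [dtr_fit()] or
#'   [reference_rules()]).
#' @return Object of class `dtr_value_report`: per-patient data frame
#'   (`patient_id`, `observed`, `counterfactual`, `status`), medians and
#'   IQRs of both times, and the paired comparison from
#'   [compare_survival()].
#' @export
regime_value <- function(cohort, regime) {
  if (!inherits(regime, "dtr_regime")) {
    stop_invalid("`regime` must be a dtr_regime")
  }
  records <- stage_records(cohort)
  entered <- sort(unique(records$stage))
  for (k in entered) {
    if (is.null(regime$stages[[k]])) {
      stop_invalid(sprintf("regime has no rule for entered stage %d", k))
    }
  }
  pts <- cohort_patients(cohort)
  remaining <- stats::setNames(rep(0, nrow(pts)), pts$patient_id)
  seen <- stats::setNames(rep(FALSE, nrow(pts)), pts$patient_id)
  for (k in sort(entered, decreasing = TRUE)) {
    rule <- regime$stages[[k]]
    rec <- records[records$stage == k, , drop = FALSE]
    feats <- assemble_features(cohort, k, rule$terms, ids = rec$patient_id)
    s <- blip_score(rule, feats)
    a_rec <- as.integer(s > 0)
    t_plus <- rec$T + remaining[rec$patient_id]
    remaining[rec$patient_id] <-
      adjust_counterfactual(0, t_plus, s, rec$a, a_rec)
    seen[rec$patient_id] <- TRUE
  }
  obs <- outcome_time(pts)
  out <- data.frame(patient_id = pts$patient_id, observed = obs,
                    counterfactual = unname(remaining[pts$patient_id]),
                    status = pts$status, stringsAsFactors = FALSE)
  cmp <- compare_survival(out$observed, out$counterfactual)
  structure(list(
    patients = out,
    observed_median = stats::median(out$observed),
    observed_iqr = stats::quantile(out$observed, c(0.25, 0.75), names = FALSE),
    counterfactual_median = stats::median(out$counterfactual),
    counterfactual_iqr = stats::quantile(out$counterfactual, c(0.25, 0.75),
                                         names = FALSE),
    comparison = cmp
  ), class = "dtr_value_report")
}

#' @export
print.dtr_value_report <- function(x, ...) {
  f <- function(m, q) sprintf("%.1f [%.1f, %.1f]", m, q[1], q[2])
  cat("Regime value (days):\n")
  cat("  counterfactual optimal:", f(x$counterfactual_median, x$counterfactual_iqr), "\n")
  cat("  observed strategy:     ", f(x$observed_median, x$observed_iqr), "\n")
  p <- x$comparison$p.value
  cat(sprintf("  paired Wilcoxon signed-rank: p %s (n nonzero = %d)\n",
              if (is.na(p)) "NA" else if (p < 0.001) "< 0.001"
              else sprintf("= %.3g", p),
              x$comparison$n_nonzero))
  invisible(x)
}

#' Paired comparison of observed and counterfactual survival
#'
#' Wilcoxon signed-rank test on the pairs with a nonzero difference. When all
#' differences are zero (everyone already treated optimally) the result is
#' flagged degenerate with p = 1.
#'
#' @param observed Observed times, or a `dtr_value_report`.
#' @param counterfactual Counterfactual times (omit when a report is given).
#' @return List with `statistic`, `p.value`, `n_nonzero`, `degenerate`.
#' @export
compare_survival <- function(observed, counterfactual = NULL) {
  if (inherits(observed, "dtr_value_report")) {
    counterfactual <- observed$patients$counterfactual
    observed <- observed$patients$observed
  }
  d <- counterfactual - observed
  nz <- which(abs(d) > 0)
  if (!length(nz)) {
    return(list(statistic = NA_real_, p.value = 1, n_nonzero = 0L,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    counterfactual[nz], observed[nz], paired = TRUE, exact = FALSE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_nonzero = length(nz), degenerate = FALSE)
}
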