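#' Declare a model term
#'
#' A term maps one (or two, for products) raw patient variables to a column of
#' the blip or treatment-free design matrix. Transforms cover the forms used by
#' the fluid-management decision rules: identity, per-constant scaling (e.g.
#' mBP per 20 mmHg), scaled-then-squared (the quadratic mBP term), category
#' indicators (ICU unit type against its reference level), and pairwise
#' products of previously declared terms (the treatment-history interaction).
#'
#' @param name Unique label for the term (used to key coefficients).
#' @param var Source variable name in the cohort table: one of `"age"`,
#'   `"icu_type"`, `"hr"`, `"mbp"`, `"rr"`, `"temp"`, `"urine"`, `"mv"`,
#'   `"vasopressor"`, `"fluid"` (the daily liberal/restricted indicator).
#' @param day ICU day (1-based) the value is read from, or `NA` for
#'   time-constant variables such as age and unit type.
#' @param transform One of `"identity"`, `"scale"`, `"scalesq"`,
#'   `"indicator"`, `"product"`.
#' @param scale Scaling constant for `"scale"`/`"scalesq"` (value is divided
#'   by it); must be nonzero.
#' @param level Category label for `"indicator"` terms.
#' @param parents Character vector of two sibling term names for `"product"`.
#' @param forced If `TRUE`, the term is never dropped by backward elimination.
#' @return An object of class `dtr_term`.
#' @seealso [model_spec()], [blip_score()]
#' @export
term_spec <- function(name, var, day = NA_integer_,
                      transform = c("identity", "scale", "scalesq",
                                    "indicator", "product"),
                      scale = 20, level = NULL, parents = NULL,
                      forced = FALSE) {
  transform <- match.arg(transform)
  if (transform %in% c("scale", "scalesq") && (!is.numeric(scale) || scale == 0)) {
    stop_invalid(sprintf("term '%s': scale constant must be nonzero", name))
  }
  if (transform == "indicator" && is.null(level)) {
    stop_invalid(sprintf("term '%s': indicator transform needs a `level`", name))
  }
  if (transform == "product" &&
      (is.null(parents) || length(parents) != 2L || !is.character(parents))) {
    stop_invalid(sprintf("term '%s': product transform needs two parent term names", name))
  }
  structure(
    list(name = as.character(name), var = as.character(var),
         day = as.integer(day), transform = transform,
         scale = as.numeric(scale), level = level, parents = parents,
         forced = isTRUE(forced)),
    class = "dtr_term"
  )
}

#' Stage model specification
#'
#' Bundles the blip (treatment-interaction) and treatment-free term lists for
#' one decision stage, together with the significance threshold used by
#' backward elimination. An intercept is always included in both parts of the
#' design and never needs to be declared.
#'
#' @param stage Stage index, 1 to 3 (decision days 1, 3 and 5).
#' @param blip List of [term_spec()] objects entering the blip function.
#' @param treatment_free List of [term_spec()] objects for the treatment-free
#'   part; defaults to the blip list (the candidate pool is shared).
#' @param alpha Significance threshold for variable selection.
#' @return An object of class `dtr_model_spec`.
#' @export
model_spec <- function(stage, blip, treatment_free = blip, alpha = 0.05) {
  stopifnot(stage %in% 1:3)
  check_terms <- function(terms, what) {
    if (!length(terms)) return(invisible())
    if (!all(vapply(terms, inherits, logical(1), "dtr_term"))) {
      stop_invalid(sprintf("%s terms must be built with term_spec()", what))
    }
    nm <- vapply(terms, `[[`, character(1), "name")
    if (anyDuplicated(nm)) {
      stop_invalid(sprintf("duplicate %s term names: %s", what,
                           paste(nm[duplicated(nm)], collapse = ", ")))
    }
    for (t in terms) {
      if (t$transform == "product" && !all(t$parents %in% nm)) {
        stop_invalid(sprintf("term '%s': product parents must be declared terms", t$name))
      }
    }
  }
  check_terms(blip, "blip")
  check_terms(treatment_free, "treatment-free")
  structure(
    list(stage = as.integer(stage),
         blip = unname(blip), treatment_free = unname(treatment_free),
         alpha = alpha),
    class = "dtr_model_spec"
  )
}

term_names <- function(terms) vapply(terms, `[[`, character(1), "name")

# Decision day for stage k: days 1, 3, 5.
decision_day <- function(stage) 2L * as.integer(stage) - 1L

#' @export
print.dtr_model_spec <- function(x, ...) {
  cat(sprintf("Stage %d model spec (decision day %d)\n", x$stage,
              decision_day(x$stage)))
  fmt <- function(terms) {
    if (!length(terms)) return("(intercept only)")
    paste(term_names(terms), collapse = ", ")
  }
  cat("  blip terms:          ", fmt(x$blip), "\n")
  cat("  treatment-free terms:", fmt(x$treatment_free), "\n")
  cat("  selection alpha:     ", x$alpha, "\n")
  invisible(x)
}

# --- term evaluation -------------------------------------------------------

# Look up the raw value of (var, day) in a feature table. Keys are "<var>_<day>"
# with fallback to "<var>" (time-constant variables, or callers supplying
# current-day values without a suffix).
feature_value <- function(features, var, day, term_name) {
  keys <- if (is.na(day)) var else c(paste0(var, "_", day), var)
  for (k in keys) {
    if (!is.null(features[[k]])) return(features[[k]])
  }
  stop_missing(sprintf(
    "term '%s': feature '%s' not found (looked for %s)",
    term_name, var, paste(sQuote(keys), collapse = ", ")))
}

# Evaluate a term list against a feature table (data.frame or named list whose
# elements have common length n). Returns an n x length(terms) matrix with one
# named column per term; products are resolved against sibling terms.
eval_terms <- function(terms, features) {
  n <- if (is.data.frame(features)) nrow(features) else {
    if (!length(features)) 1L else length(features[[1]])
  }
  if (!length(terms)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  nm <- term_names(terms)
  out <- matrix(NA_real_, nrow = n, ncol = length(terms),
                dimnames = list(NULL, nm))
  base <- vapply(terms, function(t) t$transform != "product", logical(1))
  for (i in which(base)) {
    t <- terms[[i]]
    x <- feature_value(features, t$var, t$day, t$name)
    out[, i] <- switch(t$transform,
      identity  = as.numeric(x),
      scale     = as.numeric(x) / t$scale,
      scalesq   = (as.numeric(x) / t$scale)^2,
      indicator = as.numeric(x == t$level)
    )
  }
  for (i in which(!base)) {
    t <- terms[[i]]
    j <- match(t$parents, nm)
    if (anyNA(j)) {
      stop_invalid(sprintf("term '%s': parent terms not found", t$name))
    }
    out[, i] <- out[, j[1]] * out[, j[2]]
  }
  out
}

#' Build a design matrix from a term list
#'
#' Evaluates each term against a feature table and prepends an intercept
#' column. Feature tables use `"<var>_<day>"` column keys (for example
#' `mbp_1`, `fluid_4`), with a plain `"<var>"` key accepted as fallback;
#' [assemble_features()] produces them from a cohort table.
#'
#' @param terms List of [term_spec()] objects.
#' @param features Data frame or named list of raw feature values.
#' @return Numeric matrix with an `(Intercept)` column followed by one column
#'   per term.
#' @export
term_matrix <- function(terms, features) {
  m <- eval_terms(terms, features)
  cbind(`(Intercept)` = rep(1, nrow(m)), m)
}

# --- serialization (shared by regime JSON and spec configs) ----------------

term_to_list <- function(t) {
  out <- list(name = t$name, var = t$var, transform = t$transform)
  if (!is.na(t$day)) out$day <- t$day
  if (t$transform %in% c("scale", "scalesq")) out$scale <- t$scale
  if (!is.null(t$level)) out$level <- t$level
  if (!is.null(t$parents)) out$parents <- t$parents
  if (isTRUE(t$forced)) out$forced <- TRUE
  out
}

term_from_list <- function(x) {
  term_spec(name = x$name, var = x$var, day = x$day %||% NA_integer_,
            transform = x$transform, scale = x$scale %||% 20,
            level = x$level, parents = unlist(x$parents),
            forced = isTRUE(x$forced))
}

spec_to_list <- function(spec) {
  list(stage = spec$stage,
       alpha = spec$alpha,
       blip = lapply(spec$blip, term_to_list),
       treatment_free = lapply(spec$treatment_free, term_to_list))
}

spec_from_list <- function(x) {
  model_spec(stage = x$stage,
             blip = lapply(x$blip, term_from_list),
             treatment_free = lapply(x$treatment_free %||% x$blip,
                                     term_from_list),
             alpha = x$alpha %||% 0.05)
}
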