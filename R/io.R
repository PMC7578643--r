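# Cohort CSV, regime JSON and config (YAML/JSON) serialization. Floats are
# written with 17 significant digits so that written artifacts reload to
# objects reproducing identical downstream numbers.

cohort_required_cols <- function() cohort_columns()[1:15]
cohort_optional_cols <- function() c("paco2", "wbc", "band_pct", "infection")

validate_cohort <- function(df) {
  if (!is.data.frame(df)) stop_schema("cohort must be a data frame")
  req <- cohort_required_cols()
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop_schema(paste("cohort is missing mandatory column(s):",
                      paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(df), c(req, cohort_optional_cols()))
  if (length(unknown)) {
    stop_schema(paste("cohort has unknown column(s):",
                      paste(unknown, collapse = ", ")))
  }
  if (!nrow(df)) return(invisible(df))
  num_cols <- c("day", "age", "hr", "mbp", "rr", "temp", "urine_ml", "mv",
                "vasopressor", "fluid_ml_per_kg", "death_time",
                "discharge_time",
                intersect(c("paco2", "wbc", "band_pct"), names(df)))
  for (cl in num_cols) {
    x <- df[[cl]]
    if (is.logical(x) && all(is.na(x))) next  # all-NA column from CSV
    if (!is.numeric(x)) {
      bad <- which(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))
      stop_schema(sprintf("column '%s' is not numeric (e.g. row %s)", cl,
                          paste(utils::head(bad, 3), collapse = ", ")))
    }
  }
  key <- paste(df$patient_id, df$day)
  if (anyDuplicated(key)) {
    stop_schema(sprintf("duplicated (patient, day) row(s): %s",
                        paste(utils::head(which(duplicated(key)), 3),
                              collapse = ", ")))
  }
  if (!all(df$status %in% c("died", "discharged_alive"))) {
    stop_schema("status must be 'died' or 'discharged_alive'")
  }
  first <- !duplicated(df$patient_id)
  has_death <- !is.na(df$death_time[first])
  has_disch <- !is.na(df$discharge_time[first])
  if (any(has_death == has_disch)) {
    bad <- df$patient_id[first][has_death == has_disch]
    stop_malformed(paste(
      "exactly one of death_time/discharge_time must be present; offending patient(s):",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  days <- split(df$day, df$patient_id)
  ok <- vapply(days, function(d) all(sort(d) == seq_along(d)), logical(1))
  if (!all(ok)) {
    stop_malformed(paste("daily records must cover days 1..D without gaps;",
                         "offending patient(s):",
                         paste(utils::head(names(days)[!ok], 5), collapse = ", ")))
  }
  invisible(df)
}

#' Read a patient-day cohort CSV
#'
#' Loads and validates a cohort table: mandatory schema columns, numeric
#' vitals, no duplicated (patient, day) rows, exactly one of
#' death/discharge time per patient, and gap-free daily records starting at
#' day 1. Rows are normalized to (patient_id, day) order.
#'
#' @param path CSV file path.
#' @return A validated `dtr_cohort` data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
  df <- df[order(df$patient_id, df$day), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dtr_cohort", "data.frame")
  df
}

#' Write a cohort CSV
#'
#' Floats are serialized with 17 significant digits so a written cohort
#' reloads bit-identically.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]])) {
      x <- sprintf("%.17g", out[[cl]])
      x[is.na(out[[cl]])] <- NA
      out[[cl]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

provenance_block <- function(seed = NULL) {
  out <- list(package = "fluiddtr",
              version = as.character(utils::packageVersion("fluiddtr")))
  if (!is.null(seed)) out$seed <- as.integer(seed)
  out
}

rule_to_list <- function(rule) {
  list(stage = rule$stage,
       terms = lapply(rule$terms, term_to_list),
       coef = as.list(rule$coef))
}

rule_from_list <- function(x) {
  decision_rule(stage = x$stage,
                terms = lapply(x$terms, term_from_list),
                coef = unlist(x$coef))
}

#' Write a regime to JSON
#'
#' Serializes a `dtr_regime` (stage, term definitions with transforms,
#' coefficients) together with a provenance block. Coefficients are written
#' with 17 significant digits; a reloaded regime reproduces identical blip
#' scores.
#'
#' @param regime A `dtr_regime`.
#' @param path Output JSON path.
#' @param diagnostics Optional list (e.g. CI tables) stored verbatim.
#' @param seed Optional seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_regime <- function(regime, path, diagnostics = NULL, seed = NULL) {
  doc <- list(
    provenance = c(provenance_block(seed),
                   list(rule_provenance = regime$provenance)),
    stages = lapply(Filter(Negate(is.null), regime$stages), rule_to_list)
  )
  if (!is.null(diagnostics)) doc$diagnostics <- diagnostics
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a regime from JSON
#'
#' @param path JSON file written by [write_regime()].
#' @return A `dtr_regime`.
#' @export
read_regime <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- vector("list", 3L)
  for (x in doc$stages) {
    rules[[x$stage]] <- rule_from_list(x)
  }
  new_regime(rules, provenance = doc$provenance$rule_provenance %||% "loaded")
}

read_config_file <- function(path, simplify = TRUE) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = simplify)
  }
}

#' Read simulation parameters from a YAML/JSON config
#'
#' Top-level entries override the [sim_params()] defaults; `psi_star` and
#' `beta_star` may be given as named lists per stage and are coerced to the
#' named vectors the generator expects. Model specifications themselves are
#' configured via [read_specs()].
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return A `dtr_sim_params` object.
#' @export
read_sim_params <- function(path) {
  cfg <- read_config_file(path)
  for (f in c("psi_star", "beta_star")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- lapply(cfg[[f]], unlist)
  }
  if (!is.null(cfg$sigma)) cfg$sigma <- as.numeric(unlist(cfg$sigma))
  do.call(sim_params, cfg)
}

#' Read model specifications from a YAML/JSON config
#'
#' The file holds a list of stage entries, each with `stage`, `alpha`, and
#' `blip` / `treatment_free` term lists (fields `name`, `var`, `day`,
#' `transform`, `scale`, `level`, `parents`, `forced`).
#'
#' @param path Config file path.
#' @return A `dtr_specs` list of [model_spec()] objects.
#' @export
read_specs <- function(path) {
  cfg <- read_config_file(path, simplify = FALSE)
  if (!is.null(cfg$stages)) cfg <- cfg$stages
  out <- vector("list", 3L)
  for (x in cfg) {
    s <- spec_from_list(x)
    out[[s$stage]] <- s
  }
  if (any(vapply(out, is.null, logical(1)))) {
    stop_schema("spec config must define stages 1, 2 and 3")
  }
  structure(out, class = "dtr_specs")
}

#' Write model specifications to JSON
#'
#' @param specs A `dtr_specs` list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_specs <- function(specs, path) {
  doc <- list(stages = lapply(specs, spec_to_list))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              null = "null", pretty = TRUE), path)
  invisible(path)
}
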