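# Internal helpers: condition constructors, probability clipping, feature lookup.

dtr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dtr_error")))
}

stop_invalid     <- function(msg) dtr_error(msg, "dtr_invalid_error")
stop_missing     <- function(msg) dtr_error(msg, "dtr_missing_data_error")
stop_schema      <- function(msg) dtr_error(msg, "dtr_schema_error")
stop_malformed   <- function(msg) dtr_error(msg, "dtr_malformed_error")
stop_degenerate  <- function(msg) dtr_error(msg, "dtr_degenerate_error")
stop_collinear   <- function(msg) dtr_error(msg, "dtr_collinearity_error")
stop_novertex    <- function(msg) dtr_error(msg, "dtr_novertex_error")

# Fitted probabilities are clipped away from 0/1 so that inverse-probability
# weights stay bounded.
PROB_CLIP <- c(0.01, 0.99)

clip_prob <- function(p, lo = PROB_CLIP[1], hi = PROB_CLIP[2]) {
  pmin(pmax(p, lo), hi)
}

# Evaluate generator/estimator randomness without disturbing the caller's RNG
# stream; `seed` fully determines the output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
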