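# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exclusion errors carry their own condition class so callers (e.g. the
# feature-table builder) can drop a subject instead of aborting the run.
abort_exclusion <- function(msg, rule = msg) {
  stop(errorCondition(msg, rule = rule,
                      class = c("macroeeg_exclusion", "error")))
}

is_exclusion <- function(e) inherits(e, "macroeeg_exclusion")

# Evaluate an expression under a fixed seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive n independent sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
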