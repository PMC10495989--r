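# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Division with a guard against vanishing denominators.  Features produced by
# ratio formulas must stay finite so downstream tables remain rectangular;
# any denominator with |d| < eps yields `fill` and (optionally) a warning.
safe_div <- function(num, den, eps = 1e-12, fill = 0, warn = FALSE, what = NULL) {
  bad <- !is.finite(den) | abs(den) < eps
  out <- num / den
  if (any(bad)) {
    out[bad] <- fill
    if (warn) {
      warning(sprintf("near-zero denominator in %s; value set to %g",
                      if (is.null(what)) "feature" else what, fill),
              call. = FALSE)
    }
  }
  out
}

# Stratified fold assignment: every class is spread as evenly as possible
# across folds.  Deterministic given `seed`.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  folds <- integer(n)
  rng <- local_rng(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# A small self-contained RNG wrapper.  All stochastic code in the package
# draws through one of these so that a seed fully determines the run without
# touching the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      })
      f(...)
    }
  }
  env$runif <- with_state(stats::runif)
  env$rnorm <- with_state(stats::rnorm)
  env$sample_int <- with_state(function(n, size = n, replace = FALSE)
    sample.int(n, size = size, replace = replace))
  env$rpois <- with_state(stats::rpois)
  # derive a child seed (kept below 2^31) for nested seeded components
  env$child_seed <- with_state(function() sample.int(.Machine$integer.max, 1L))
  env
}

# Run `expr` with the global RNG temporarily seeded; restores state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
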