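# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of (spec, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed derived from one global seed; kept well below
# .Machine$integer.max so downstream set.seed() never overflows.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

assert_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(sprintf("'%s' must be a single positive integer, got %s",
                 name, paste(x, collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, open = TRUE) {
  ok <- length(x) == 1L && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x < 1)
  if (!ok) {
    stop(sprintf("'%s' must lie in %s, got %s", name,
                 if (open) "(0, 1)" else "[0, 1)", x), call. = FALSE)
  }
  invisible(as.numeric(x))
}
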