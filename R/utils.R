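# Internal helpers shared across modules.

# Abort with a classed condition so callers/tests can match on error class.
abort_fib <- function(msg, class) {
  stop(structure(
    class = c(class, "fibdamage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed, so independent
# stages get independent, reproducible randomness.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
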