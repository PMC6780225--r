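# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
# All exported simulators take an explicit `seed`; nothing uses global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    withr::with_seed(as.integer(seed), expr)
  } else {
    expr
  }
}

# Deterministically derive a child seed from a master seed and a stage label,
# keeping the result inside 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629L)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

# Nearly-equal test for floating-point invariant checks.
near <- function(x, y, tol = 1e-8) abs(x - y) <= tol * pmax(1, abs(x), abs(y))
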