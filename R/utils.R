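# internal helpers: seeding, validation

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Deterministically derive `n` child seeds from one parent seed.
# Kept strictly below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(2147483646L, n))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
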