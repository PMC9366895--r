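# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one master seed into per-stage seeds, kept inside
# the 32-bit integer range R requires.
fan_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

curie_prefix <- function(id) sub(":.*$", "", id)
curie_local <- function(id) sub("^[^:]*:", "", id)

`%||%` <- rlang::`%||%`

# shared validation for two-column id tables read from TSV
check_two_cols <- function(x, what) {
  if (ncol(x) < 2L) {
    abort(sprintf("%s must have at least two columns, got %d", what, ncol(x)))
  }
  x
}
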