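# Run code under a temporary RNG state so fitting functions are seeded
# without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derived sub-seeds stay inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629) + 1L
}

is_hard_calls <- function(v) {
  v <- v[is.finite(v)]
  length(unique(v)) <= 3L && all(abs(v - round(v)) < 1e-8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
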