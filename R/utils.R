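# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive n reproducible sub-seeds (< 2^31) from one seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# linear interpolation of a (homeostatic, reactive) parameter pair by phi
interp_pair <- function(pair, phi) pair[1] + phi * (pair[2] - pair[1])

`%||%` <- function(a, b) if (is.null(a)) b else a
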