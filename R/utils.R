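# Run code under a fixed RNG state, restoring the caller's state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from one parent seed, staying inside the
# 32-bit integer range.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max, n))
}
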