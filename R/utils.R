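## internal helpers

## Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
## state afterwards. Every stochastic operation in the package goes through
## this so that generators are pure functions of their spec (seed included)
## and never leak hidden global state.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## derive a child seed from a base seed and an index, kept within 32-bit range
.childSeed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 1009) %% 2147483629)
}
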