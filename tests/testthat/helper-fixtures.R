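## shared helpers for the test suite

## evaluate an expression under a temporary seed, restoring RNG state
.withSeedHelper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## brute-force SCI: sort, average the extreme m values
bruteForceSci <- function(v, tailFraction = 0.05) {
  m <- max(1L, floor(tailFraction * length(v)))
  srt <- sort(v)
  mean(rev(srt)[seq_len(m)]) / mean(srt[seq_len(m)])
}

## population (divide-by-n) coefficient-of-variation squared
directSignalVariance <- function(v) {
  mu <- mean(v)
  mean((v - mu)^2) / mu^2
}

## brute-force all-pairs bound-unit count per chain for one frame
bruteForceContacts <- function(frame, system) {
  L <- system@boxLength
  cut <- system@contactCutoff
  unitIdx <- unlist(system@complexes, use.names = FALSE)
  sapply(system@motifIndices, function(mi) {
    n <- 0L
    for (u in unitIdx) {
      bound <- FALSE
      for (m in mi) {
        d <- frame[u, ] - frame[m, ]
        d <- d - L * round(d / L)
        if (sqrt(sum(d^2)) <= cut) bound <- TRUE
      }
      if (bound) n <- n + 1L
    }
    n
  })
}

## a minimal two-chain system with hand-placed coordinates for contact tests:
## chain beads along x at y = 10 (chain 1) / 20 (chain 2), z = 10; bead b sits
## at x = 3.4 (b - 1) + 2, and beads 2..5 of each 6-bead chain are motifs
handSystem <- function(unitPos, boxNm = 40) {
  sys <- buildSystem(1L, units = 2L, nDna = 2L, boxNm = boxNm,
                     beadsPerChain = 6L, wellDepth = 0, seed = 1L)
  pos <- sys@positions
  for (c_ in 1:2) {
    idx <- sys@dnaChains[[c_]]
    for (b in seq_along(idx)) {
      pos[idx[b], ] <- c(3.4 * (b - 1) + 2, 10 * c_, 10)
    }
  }
  uIdx <- unlist(sys@complexes)
  for (u in seq_along(uIdx)) pos[uIdx[u], ] <- unitPos[u, ]
  pos <- pos - boxNm * floor(pos / boxNm)
  methods::slot(sys, "positions") <- pos
  sys
}
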