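## Reduced coarse-grained simulator: oligomeric complexes of binding units
## and motif-bearing DNA chains in a periodic box, overdamped Langevin
## dynamics, contact counting at 1.2 nm, and the oligomer-state scan.
##
## Resolution: one bead per binding unit (one monomeric complex) and ~10 bp
## per DNA bead. Energies are in kT, lengths in nm, time in diffusive units.

#' The CORE-containing promoter fragment sequence
#'
#' Returns the 169-nt double-helical DNA fragment carrying the four CO
#' response elements used for the binding simulations, read from the
#' packaged FASTA fixture.
#'
#' @return A single character string (DNA sequence).
#' @export
corePromoterFragment <- function() {
  path <- system.file("extdata", "FT_promoter_CORE_fragment.fasta",
                      package = "condensateR")
  lines <- readLines(path)
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

#' Build a reduced oligomer-DNA system
#'
#' Places `floor(units / oligomerState)` oligomeric complexes (left-over
#' units enter as monomers) and `nDna` DNA chains uniformly at random in a
#' cubic periodic box. Each DNA chain is a straight line of beads at ~10 bp
#' per bead with four evenly spaced motif beads; each complex is a linear
#' chain of `oligomerState` binding-unit beads joined by soft tethers whose
#' rest length matches the motif spacing (the spacer-matching condition for
#' multivalent engagement). Unit beads are placed with a minimum mutual
#' separation; repeated failure to pack is an error.
#'
#' Defaults mirror the study composition: 60 binding units, 15 DNA chains,
#' a 120 nm box and a 1.2 nm contact cutoff.
#'
#' @param oligomerState units per complex, 1-5.
#' @param units total number of binding units (default 60).
#' @param nDna number of DNA chains (default 15).
#' @param boxNm cubic box edge, nm (default 120).
#' @param wellDepth unit-motif attractive well depth, kT (default 9, the
#'   partial-occupancy regime at the desk-scale composition).
#' @param bondLength DNA bead spacing, nm (default 3.4, ~10 bp).
#' @param unitBondLength intra-complex link rest length, nm (default 6.8,
#'   matching the motif spacing so oligomer arms can engage adjacent sites
#'   - the spacer-matching condition for multivalent binding).
#' @param beadsPerChain DNA beads per chain; the default matches the 169-nt
#'   CORE fragment at ~10 bp per bead.
#' @param temperature reduced temperature (kT units, default 1).
#' @param contactCutoff contact distance, nm (default 1.2).
#' @param seed integer seed (governs complex placement, and chain placement
#'   unless `chainSeed` is given).
#' @param chainSeed optional separate seed for DNA-chain placement; state
#'   scans use it to keep the chain geometry identical across oligomer
#'   states so that state comparisons are paired.
#' @param maxAttempts placement attempts per complex before failing.
#' @return A [ReducedSystem-class].
#' @examples
#' sys <- buildSystem(3, units = 12, nDna = 2, boxNm = 40, seed = 1)
#' nBindingUnits(sys)
#' @export
buildSystem <- function(oligomerState, units = 60L, nDna = 15L, boxNm = 120,
                        wellDepth = 9, bondLength = 3.4, unitBondLength = 6.8,
                        beadsPerChain = NULL, temperature = 1,
                        contactCutoff = 1.2, seed = 1L, chainSeed = NULL,
                        maxAttempts = 2000L) {
  s <- as.integer(oligomerState)
  if (s < 1L || s > 5L) stop("oligomerState must be in 1..5")
  units <- as.integer(units)
  if (units < 1L) stop("units must be >= 1")
  if (is.null(beadsPerChain)) {
    beadsPerChain <- as.integer(round(nchar(corePromoterFragment()) / 10))
  }
  nS <- units %/% s
  rem <- units %% s
  sizes <- c(rep(s, nS), rep(1L, rem))
  ## four motif beads at uniform ~20 bp (2-bead) spacing centred on the
  ## chain: a tandem cis-element block whose spacing the intra-complex
  ## tethers can span (the spacer-matching condition for avidity)
  dSite <- min(2L, max(1L, (beadsPerChain - 1L) %/% 3L))
  startSite <- max(1L, (beadsPerChain - 3L * dSite + 1L) %/% 2L)
  motifLocal <- pmin(startSite + (0:3) * dSite, beadsPerChain)
  if (is.null(chainSeed)) chainSeed <- seed
  chainsOut <- .withSeed(chainSeed, {
    pos <- matrix(numeric(0), 0, 3)
    dnaChains <- vector("list", nDna)
    motifIndices <- vector("list", nDna)
    for (c_ in seq_len(nDna)) {
      origin <- runif(3, 0, boxNm)
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      beads <- t(vapply(seq_len(beadsPerChain) - 1L,
                        function(b) origin + b * bondLength * dirv,
                        numeric(3)))
      idx <- nrow(pos) + seq_len(beadsPerChain)
      pos <- rbind(pos, beads)
      dnaChains[[c_]] <- idx
      motifIndices[[c_]] <- idx[motifLocal]
    }
    list(pos = pos, dnaChains = dnaChains, motifIndices = motifIndices)
  })
  .withSeed(seed, {
    pos <- chainsOut$pos
    dnaChains <- chainsOut$dnaChains
    motifIndices <- chainsOut$motifIndices
    complexes <- vector("list", length(sizes))
    unitRows <- integer(0)
    for (k in seq_along(sizes)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        origin <- runif(3, 0, boxNm)
        dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        beads <- t(vapply(seq_len(sizes[k]) - 1L,
                          function(b) origin + b * unitBondLength * dirv,
                          numeric(3)))
        if (length(unitRows) > 0L) {
          prev <- pos[unitRows, , drop = FALSE]
          minD2 <- min(vapply(seq_len(nrow(beads)), function(i) {
            d <- .minImageDiff(prev, beads[i, ], boxNm)
            min(rowSums(d^2))
          }, numeric(1)))
          if (minD2 < 2^2) next
        }
        idx <- nrow(pos) + seq_len(sizes[k])
        pos <- rbind(pos, beads)
        complexes[[k]] <- idx
        unitRows <- c(unitRows, idx)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("packing failure: could not place complex ", k, " after ",
             maxAttempts, " attempts")
      }
    }
    pos <- pos - boxNm * floor(pos / boxNm)
    new("ReducedSystem", boxLength = boxNm, positions = pos,
        dnaChains = dnaChains, motifIndices = motifIndices,
        complexes = complexes, oligomerState = s,
        contactCutoff = contactCutoff, bindingWellDepth = wellDepth,
        temperature = temperature, bondLength = bondLength,
        unitBondLength = unitBondLength, seed = as.integer(seed))
  })
}

## rows of `mat` minus vector `v`, minimum image
.minImageDiff <- function(mat, v, L) {
  d <- sweep(mat, 2, v)
  d - L * round(d / L)
}

## bond list of a system: DNA backbone springs + intra-complex links
.systemBonds <- function(system) {
  dna <- do.call(rbind, lapply(system@dnaChains, function(idx) {
    if (length(idx) < 2L) return(NULL)
    cbind(idx[-length(idx)], idx[-1])
  }))
  unit <- do.call(rbind, lapply(system@complexes, function(idx) {
    if (length(idx) < 2L) return(NULL)
    cbind(idx[-length(idx)], idx[-1])
  }))
  nDnaBonds <- if (is.null(dna)) 0L else nrow(dna)
  nUnitBonds <- if (is.null(unit)) 0L else nrow(unit)
  triplets <- do.call(rbind, lapply(system@dnaChains, function(idx) {
    if (length(idx) < 3L) return(NULL)
    cbind(idx[seq_len(length(idx) - 2L)], idx[seq_len(length(idx) - 2L) + 1L],
          idx[seq_len(length(idx) - 2L) + 2L])
  }))
  if (is.null(triplets)) triplets <- matrix(integer(0), 0L, 3L)
  list(bonds = rbind(dna, unit),
       rest = c(rep(system@bondLength, nDnaBonds),
                rep(system@unitBondLength, nUnitBonds)),
       isUnit = c(rep(FALSE, nDnaBonds), rep(TRUE, nUnitBonds)),
       triplets = triplets)
}

#' Run overdamped Langevin dynamics
#'
#' Integrates the reduced system with the overdamped Langevin update
#' `dx = F dt + sqrt(2 T dt) eta` (unit mobility, energies in kT, lengths in
#' nm), recording coordinates every `stride` steps. Forces: harmonic DNA and
#' intra-complex springs, soft repulsion between binding units (which also
#' enforces at most one unit per motif well), and a short-range attractive
#' well of depth `bindingWellDepth` between units and motif beads with range
#' equal to the contact cutoff.
#'
#' @param system a [ReducedSystem-class].
#' @param nSteps number of integration steps.
#' @param dt time step (diffusive units; default 0.008 keeps the stiffest
#'   spring stable).
#' @param stride steps between recorded frames.
#' @param seed integer seed (same seed and system give an identical
#'   trajectory).
#' @param kBond DNA backbone spring constant, kT/nm^2.
#' @param kUnit intra-complex tether spring constant, kT/nm^2 (default 3:
#'   semi-flexible linkers that hold oligomer arms near the motif spacing,
#'   concentrating them at neighbouring sites - the lever that sets the
#'   multivalent bridging strength without deepening the wells).
#' @param kRep unit-unit soft-repulsion constant, kT/nm^2 (default 60).
#' @param repRange unit-unit repulsion range, nm (default 2.4 = twice the
#'   contact cutoff, so two units cannot occupy one motif well - one
#'   complex footprint per CORE).
#' @param kAngle DNA bending stiffness, kT/rad^2 (default 20, giving the
#'   chain a persistence length of kAngle x bond length ~ 68 nm, i.e. the
#'   fragment behaves as a nearly straight double helix).
#' @return A list of class `"CgTrajectory"`: `frames` (N x 3 x nFrames
#'   array), `times`, `system`, and the integration parameters.
#' @export
runDynamics <- function(system, nSteps = 1000000L, dt = 0.008, stride = 1000L,
                        seed = 1L, kBond = 30, kUnit = 3, kRep = 60,
                        repRange = 2.4, kAngle = 20) {
  stopifnot(is(system, "ReducedSystem"))
  if (dt * max(kBond, kUnit) > 0.5) {
    stop("dt too large for the stiffest spring constant")
  }
  bl <- .systemBonds(system)
  bondK <- ifelse(bl$isUnit, kUnit, kBond)
  unitIdx <- unlist(system@complexes, use.names = FALSE)
  motifIdx <- unlist(system@motifIndices, use.names = FALSE)
  res <- .withSeed(seed, {
    .cgLangevinRun(system@positions, system@boxLength,
                   bl$bonds - 1L, bl$rest, bondK,
                   bl$triplets - 1L, kAngle,
                   as.integer(unitIdx - 1L), as.integer(motifIdx - 1L),
                   repRange, kRep,
                   system@bindingWellDepth, system@contactCutoff,
                   as.integer(nSteps), dt, as.integer(stride),
                   system@temperature)
  })
  nFrames <- as.integer(nSteps) %/% as.integer(stride)
  frames <- array(res$frames, dim = c(nrow(system@positions), 3L, nFrames))
  structure(list(frames = frames,
                 times = dt * stride * seq_len(nFrames),
                 system = system,
                 params = list(nSteps = nSteps, dt = dt, stride = stride,
                               seed = as.integer(seed), kBond = kBond,
                               kUnit = kUnit, kRep = kRep,
                               repRange = repRange, kAngle = kAngle)),
            class = "CgTrajectory")
}

#' @export
print.CgTrajectory <- function(x, ...) {
  cat("CgTrajectory:", dim(x$frames)[3], "frames of",
      dim(x$frames)[1], "beads, dt =", x$params$dt,
      ", stride =", x$params$stride, "\n")
  invisible(x)
}

#' Count bound units per DNA chain in one frame
#'
#' A binding unit is bound to a chain when its minimum-image distance to any
#' motif bead of that chain is within the contact cutoff (closed boundary:
#' exactly at the cutoff counts as bound).
#'
#' @param frame N x 3 coordinate matrix (one trajectory frame), or a
#'   `"CgTrajectory"` with a `frameIndex`.
#' @param system the [ReducedSystem-class] the frame belongs to.
#' @param frameIndex frame number when `frame` is a trajectory.
#' @return Integer vector: bound-unit count per chain.
#' @export
countContacts <- function(frame, system, frameIndex = NULL) {
  if (inherits(frame, "CgTrajectory")) {
    if (is.null(frameIndex)) stop("frameIndex required for a trajectory")
    sys <- frame$system
    frame <- frame$frames[, , frameIndex]
  } else {
    sys <- system
  }
  stopifnot(is(sys, "ReducedSystem"))
  unitIdx <- unlist(sys@complexes, use.names = FALSE)
  up <- frame[unitIdx, , drop = FALSE]
  L <- sys@boxLength
  cut2 <- sys@contactCutoff^2
  allMotifs <- unlist(sys@motifIndices, use.names = FALSE)
  mp <- frame[allMotifs, , drop = FALSE]
  ## minimum-image squared distances, all units x all motif beads at once
  d2 <- matrix(0, nrow(up), nrow(mp))
  for (k in 1:3) {
    d <- outer(up[, k], mp[, k], "-")
    d <- d - L * round(d / L)
    d2 <- d2 + d * d
  }
  hit <- d2 <= cut2
  chainOf <- rep(seq_along(sys@motifIndices), lengths(sys@motifIndices))
  vapply(seq_along(sys@motifIndices), function(ch) {
    sum(rowSums(hit[, chainOf == ch, drop = FALSE]) > 0)
  }, integer(1))
}

#' Bound-count distribution over a trajectory
#'
#' Counts bound units per chain over the sampling frames (the second half of
#' the trajectory; the first half is discarded as equilibration) and
#' summarises them as a histogram with mean and SD. The standard error of
#' the mean accounts for frame-to-frame correlation via batch means.
#'
#' @param trajectory a `"CgTrajectory"` from [runDynamics()].
#' @param system optional [ReducedSystem-class] (defaults to the one stored
#'   in the trajectory).
#' @param nBatches number of batches for the batch-means SE (default 10).
#' @return A list with `counts` (frames x chains matrix), `histogram`
#'   (table over bound counts), `mean`, `sd`, `se` and `nFrames`.
#' @export
boundDistribution <- function(trajectory, system = NULL, nBatches = 10L) {
  stopifnot(inherits(trajectory, "CgTrajectory"))
  if (is.null(system)) system <- trajectory$system
  nF <- dim(trajectory$frames)[3]
  sampleIdx <- seq.int(nF %/% 2 + 1L, nF)
  if (nF < 2L || length(sampleIdx) < 1L) {
    stop("trajectory too short: all frames fall in the equilibration half")
  }
  counts <- t(vapply(sampleIdx, function(f) {
    countContacts(trajectory$frames[, , f], system)
  }, integer(length(system@dnaChains))))
  if (length(system@dnaChains) == 1L) counts <- matrix(counts, ncol = 1L)
  vals <- as.vector(counts)
  perFrame <- rowMeans(counts)
  nb <- min(nBatches, length(perFrame))
  batch <- split(perFrame, cut(seq_along(perFrame), nb, labels = FALSE))
  bm <- vapply(batch, mean, numeric(1))
  se <- if (nb > 1) sd(bm) / sqrt(nb) else NA_real_
  list(counts = counts,
       histogram = table(factor(vals, levels = 0:max(c(vals, 4)))),
       mean = mean(vals),
       sd = sqrt(mean((vals - mean(vals))^2)),
       se = se,
       nFrames = length(sampleIdx))
}

#' Analytic bound-count expectation without binding
#'
#' With the attractive well switched off, binding-unit positions are
#' uniform over the periodic box (unit-unit repulsion is translation
#' invariant and does not alter the one-body marginal), so the expected
#' number of units within the contact cutoff of a chain's four motif beads
#' is `units * 4 * (4/3) pi rc^3 / V` (motif contact spheres do not overlap
#' at the default spacing).
#'
#' @param system a [ReducedSystem-class].
#' @return Expected bound-unit count per chain.
#' @export
randomContactExpectation <- function(system) {
  stopifnot(is(system, "ReducedSystem"))
  vSphere <- 4 / 3 * pi * system@contactCutoff^3
  nBindingUnits(system) * 4 * vSphere / system@boxLength^3
}

#' Scan mean bound count across oligomer states
#'
#' Runs the binding simulation for each oligomer state and seed, reporting
#' the per-state mean (over seeds) of the mean bound-unit count per chain
#' and the Spearman correlation between state and mean (the avidity
#' statistic). Defaults use the desk-scale composition (16 units, 4 chains,
#' 60 nm box) with the study ratios preserved; pass `units = 60, nDna = 15,
#' boxNm = 120` for the full composition.
#'
#' @param states oligomer states to scan (default 1:5, >= 2 required).
#' @param seeds integer seeds per state (>= 1; a single seed leaves SD
#'   undefined and flags the scan).
#' @param units,nDna,boxNm,wellDepth system composition, see [buildSystem()].
#' @param nSteps,dt,stride integration settings, see [runDynamics()].
#' @param ... further arguments to [buildSystem()].
#' @return A list with `table` (data frame: state, mean, sd, se), `perRun`
#'   (data frame: state, seed, mean), `spearman`, and `singleSeed` flag.
#' @export
scanOligomerStates <- function(states = 1:5, seeds = 1:3, units = 32L,
                               nDna = 8L, boxNm = 76, wellDepth = 9,
                               nSteps = 2000000L, dt = 0.008,
                               stride = 1000L, ...) {
  states <- sort(unique(as.integer(states)))
  if (length(states) < 2L) stop("need at least 2 oligomer states")
  if (length(seeds) < 1L) stop("need at least 1 seed")
  perRun <- do.call(rbind, lapply(states, function(s) {
    do.call(rbind, lapply(seeds, function(sd_) {
      ## chain geometry depends only on the seed index, so comparisons
      ## across oligomer states are paired
      sys <- buildSystem(s, units = units, nDna = nDna, boxNm = boxNm,
                         wellDepth = wellDepth, seed = .childSeed(sd_, s),
                         chainSeed = .childSeed(sd_, 777L), ...)
      traj <- runDynamics(sys, nSteps = nSteps, dt = dt, stride = stride,
                          seed = .childSeed(sd_, 100L + s))
      bd <- boundDistribution(traj)
      data.frame(state = s, seed = sd_, mean = bd$mean)
    }))
  }))
  tab <- do.call(rbind, lapply(states, function(s) {
    m <- perRun$mean[perRun$state == s]
    data.frame(state = s, mean = mean(m),
               sd = if (length(m) > 1) sd(m) else NA_real_,
               se = if (length(m) > 1) sd(m) / sqrt(length(m)) else NA_real_)
  }))
  rho <- suppressWarnings(cor(tab$state, tab$mean, method = "spearman"))
  list(table = tab, perRun = perRun, spearman = rho,
       singleSeed = length(seeds) == 1L)
}

#' Metropolis Monte-Carlo sampling of binding-unit positions
#'
#' Equilibrium cross-check for the Langevin engine: unit beads are displaced
#' by uniform trial moves accepted by the Metropolis rule under the same
#' energy function (unit-motif well, unit-unit soft repulsion, intra-complex
#' springs); DNA beads are held fixed. Intended for small systems, e.g. a
#' single unit and one motif-bearing chain, where the two-state Boltzmann
#' occupancy is known.
#'
#' @param system a [ReducedSystem-class].
#' @param nSweeps Monte-Carlo sweeps (one trial move per unit per sweep).
#' @param maxStep maximum displacement per axis, nm.
#' @param sampleStride sweeps between samples.
#' @param seed integer seed.
#' @param kRep,repRange unit-unit repulsion parameters (as in
#'   [runDynamics()]).
#' @param kUnit intra-complex tether spring constant.
#' @return A list with `boundCounts` (samples x chains matrix) and
#'   `acceptance` rate.
#' @export
runMonteCarlo <- function(system, nSweeps = 20000L, maxStep = 1.5,
                          sampleStride = 10L, seed = 1L, kRep = 60,
                          repRange = 2.4, kUnit = 3) {
  stopifnot(is(system, "ReducedSystem"))
  L <- system@boxLength
  eps <- system@bindingWellDepth
  rc <- system@contactCutoff
  temp <- system@temperature
  pos <- system@positions
  unitIdx <- unlist(system@complexes, use.names = FALSE)
  motifIdx <- unlist(system@motifIndices, use.names = FALSE)
  partner <- lapply(unitIdx, function(i) {
    cmp <- system@complexes[[which(vapply(system@complexes,
                                          function(ix) i %in% ix,
                                          logical(1)))[1]]]
    pozn <- match(i, cmp)
    cmp[c(pozn - 1L, pozn + 1L)[c(pozn > 1L, pozn < length(cmp))]]
  })
  uEnergy <- function(p, i, pos) {
    e <- 0
    mp <- pos[motifIdx, , drop = FALSE]
    d2 <- rowSums(.minImageDiff(mp, p, L)^2)
    w <- d2 < rc^2
    if (any(w)) e <- e - eps * sum((1 - d2[w] / rc^2)^2)
    others <- setdiff(unitIdx, i)
    if (length(others)) {
      d2o <- rowSums(.minImageDiff(pos[others, , drop = FALSE], p, L)^2)
      wo <- d2o < repRange^2
      if (any(wo)) e <- e + 0.5 * kRep * sum((repRange - sqrt(d2o[wo]))^2)
    }
    prt <- partner[[match(i, unitIdx)]]
    if (length(prt)) {
      dp <- sqrt(rowSums(.minImageDiff(pos[prt, , drop = FALSE], p, L)^2))
      e <- e + 0.5 * kUnit * sum((dp - system@unitBondLength)^2)
    }
    e
  }
  .withSeed(seed, {
    nAcc <- 0L; nTry <- 0L
    samples <- list()
    for (sw in seq_len(nSweeps)) {
      for (i in unitIdx) {
        old <- pos[i, ]
        trial <- old + runif(3, -maxStep, maxStep)
        trial <- trial - L * floor(trial / L)
        dE <- uEnergy(trial, i, pos) - uEnergy(old, i, pos)
        nTry <- nTry + 1L
        if (dE <= 0 || runif(1) < exp(-dE / temp)) {
          pos[i, ] <- trial
          nAcc <- nAcc + 1L
        }
      }
      if (sw %% sampleStride == 0L) {
        samples[[length(samples) + 1L]] <- countContacts(pos, system)
      }
    }
    list(boundCounts = do.call(rbind, samples), acceptance = nAcc / nTry)
  })
}
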