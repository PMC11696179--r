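test_that("system composition follows the oligomer state", {
  s1 <- buildSystem(1L, units = 60L, nDna = 15L, boxNm = 120, seed = 1)
  expect_equal(length(s1@complexes), 60L)
  expect_equal(length(s1@dnaChains), 15L)
  expect_equal(nBindingUnits(s1), 60L)
  expect_true(all(lengths(s1@motifIndices) == 4L))

  s3 <- buildSystem(3L, units = 60L, nDna = 15L, boxNm = 120, seed = 2)
  expect_equal(length(s3@complexes), 20L)
  expect_equal(nBindingUnits(s3), 60L)

  s5 <- buildSystem(5L, units = 60L, nDna = 15L, boxNm = 120, seed = 3)
  expect_equal(length(s5@complexes), 12L)

  ## remainder units enter as monomers
  s5r <- buildSystem(5L, units = 17L, nDna = 4L, boxNm = 60, seed = 4)
  expect_equal(sort(unique(lengths(s5r@complexes))), c(1L, 5L))
  expect_equal(nBindingUnits(s5r), 17L)

  ## all coordinates wrapped into the box
  expect_true(all(s1@positions >= 0 & s1@positions < 120))

  expect_error(buildSystem(2L, units = 40L, nDna = 2L, boxNm = 8,
                           maxAttempts = 10L), "packing failure")
})

test_that("contact counting applies the closed 1.2 nm cutoff", {
  ## motif beads of chain 1 sit at x = 5.4, 8.8, 12.2, 15.6 (y = 10, z = 10)
  sys <- handSystem(rbind(c(5.4, 10 + 1.0, 10),    # 1.0 nm from a motif bead
                          c(5.4, 20 + 1.5, 10)))   # 1.5 nm away
  counts <- countContacts(sys@positions, sys)
  expect_equal(counts, c(1L, 0L))

  ## exactly at the cutoff counts as bound (closed boundary), and a unit
  ## sitting 1 nm from the chain's non-motif end bead (x = 2) is not bound
  sysEq <- handSystem(rbind(c(5.4, 10 + 1.2, 10),
                            c(2, 10 + 1.0, 10)))
  expect_equal(countContacts(sysEq@positions, sysEq), c(1L, 0L))
})

test_that("contact decisions are invariant under periodic image shifts", {
  set.seed(31)
  sys <- buildSystem(2L, units = 8L, nDna = 3L, boxNm = 30, seed = 5)
  pos <- sys@positions
  base <- countContacts(pos, sys)
  for (shift in list(c(30, 0, 0), c(0, -30, 30), c(15, 15, 15))) {
    shifted <- sweep(pos, 2, shift, "+")
    shifted <- shifted - 30 * floor(shifted / 30)
    expect_equal(countContacts(shifted, sys), base)
  }
})

test_that("fast contact counting agrees with a brute-force all-pairs
           recount", {
  sys <- buildSystem(3L, units = 12L, nDna = 4L, boxNm = 30, wellDepth = 6,
                     seed = 6)
  traj <- runDynamics(sys, nSteps = 4000, stride = 500, seed = 6)
  for (f in seq_len(dim(traj$frames)[3])) {
    frame <- traj$frames[, , f]
    expect_equal(countContacts(frame, sys), bruteForceContacts(frame, sys))
  }
})

test_that("dynamics are deterministic given the seed and conserve units", {
  sys <- buildSystem(2L, units = 8L, nDna = 2L, boxNm = 30, wellDepth = 6,
                     seed = 7)
  t1 <- runDynamics(sys, nSteps = 5000, stride = 500, seed = 11)
  t2 <- runDynamics(sys, nSteps = 5000, stride = 500, seed = 11)
  expect_identical(t1$frames, t2$frames)
  t3 <- runDynamics(sys, nSteps = 5000, stride = 500, seed = 12)
  expect_false(identical(t1$frames, t3$frames))

  ## unit conservation and wrapping in every recorded frame
  nBeads <- nrow(sys@positions)
  for (f in seq_len(dim(t1$frames)[3])) {
    frame <- t1$frames[, , f]
    expect_equal(nrow(frame), nBeads)
    expect_true(all(is.finite(frame)))
    expect_true(all(frame >= 0 & frame < 30))
  }
})

test_that("bound distribution discards the equilibration half and matches a
           direct recount", {
  sys <- buildSystem(1L, units = 6L, nDna = 2L, boxNm = 25, wellDepth = 7,
                     beadsPerChain = 6L, seed = 8)
  traj <- runDynamics(sys, nSteps = 20000, stride = 1000, seed = 8)
  bd <- boundDistribution(traj)
  nF <- dim(traj$frames)[3]
  sampled <- seq.int(nF %/% 2 + 1L, nF)
  direct <- t(vapply(sampled, function(f) {
    bruteForceContacts(traj$frames[, , f], sys)
  }, integer(2)))
  expect_equal(as.vector(bd$counts), as.vector(direct))
  expect_equal(bd$mean, mean(direct))
  expect_equal(bd$nFrames, length(sampled))
  expect_equal(sum(bd$histogram), length(direct))
})

test_that("Monte-Carlo occupancy matches the two-state Boltzmann ratio", {
  ## one monomer unit and one short chain in a small box; DNA held fixed
  eps <- 6
  sys <- buildSystem(1L, units = 1L, nDna = 1L, boxNm = 20, wellDepth = eps,
                     beadsPerChain = 6L, seed = 9)
  mc <- runMonteCarlo(sys, nSweeps = 40000L, maxStep = 3, sampleStride = 5L,
                      seed = 10)
  pHat <- mean(mc$boundCounts > 0)

  rc <- sys@contactCutoff
  zWell <- integrate(function(r) {
    exp(eps * (1 - (r / rc)^2)^2) * 4 * pi * r^2
  }, 0, rc)$value
  vWell <- 4 / 3 * pi * rc^3
  pTheory <- 4 * zWell / (4 * zWell + 20^3 - 4 * vWell)
  ## generous tolerance: samples are correlated
  se <- sqrt(pTheory * (1 - pTheory) / (nrow(mc$boundCounts) / 20))
  expect_lt(abs(pHat - pTheory), 4 * se)
  expect_gt(mc$acceptance, 0.2)
})

test_that("oligomer-state scan reports per-state summaries and flags a
           single-seed scan", {
  scan <- scanOligomerStates(states = c(1, 3), seeds = 1L, units = 6L,
                             nDna = 2L, boxNm = 30, wellDepth = 6,
                             nSteps = 10000L, stride = 500L)
  expect_true(scan$singleSeed)
  expect_true(all(is.na(scan$table$sd)))
  expect_equal(scan$table$state, c(1L, 3L))
  expect_error(scanOligomerStates(states = 2, seeds = 1:3), "at least 2")
})
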