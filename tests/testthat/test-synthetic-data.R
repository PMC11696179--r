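test_that("nucleus generator is deterministic and validates its spec", {
  a <- makeNucleusImage("spherical", seed = 5)
  b <- makeNucleusImage("spherical", seed = 5)
  expect_identical(intensities(a$image), intensities(b$image))
  c_ <- makeNucleusImage("spherical", seed = 6)
  expect_false(identical(intensities(a$image), intensities(c_$image)))

  expect_error(makeNucleusImage("diffuse", focusCount = 3),
               "if and only if")
  expect_error(makeNucleusImage("spherical", focusCount = 0),
               "if and only if")
  expect_error(makeNucleusImage("spherical", imageSize = 24L,
                                focusCount = 8L, focusRadius = 0.5),
               "too small")
  expect_error(makeNucleusImage("diffuse", meanIntensity = 0), "positive")
})

test_that("each assembly class lands in its variance bin for >= 95% of
           seeds (generator calibration)", {
  nSeeds <- 200
  inBin <- function(cls, lo, hi) {
    v <- vapply(seq_len(nSeeds), function(s) {
      as.numeric(nucleusSignalVariance(makeNucleusImage(cls,
                                                        seed = s)$image))
    }, numeric(1))
    mean(v >= lo & v <= hi)
  }
  expect_gte(inBin("diffuse", 0, 0.21 - 1e-12), 0.95)
  expect_gte(inBin("spherical", 0.21, 0.45), 0.95)
  expect_gte(inBin("aggregate", 0.45 + 1e-12, Inf), 0.95)
})

test_that("population generator conserves counts and converges to its
           weights", {
  pop <- makeNucleusPopulation(c(1, 0, 0), n = 10, seed = 1)
  expect_true(all(pop$labels == "diffuse"))

  pop75 <- makeNucleusPopulation(c(0.16, 0.36, 0.48), n = 75, seed = 2)
  expect_equal(sum(table(pop75$labels)), 75L)
  expect_equal(length(pop75$images), 75L)

  ## law of large numbers on the label stream (labels only, no images needed)
  big <- .withSeedHelper(3, sample(assemblyClasses(), 20000, replace = TRUE,
                                   prob = c(0.16, 0.36, 0.48)))
  frac <- table(factor(big, levels = assemblyClasses())) / 20000
  expect_true(all(abs(frac - c(0.16, 0.36, 0.48)) < 0.01))

  expect_error(makeNucleusPopulation(c(-0.1, 0.5, 0.6), 10), "non-negative")
  expect_error(makeNucleusPopulation(c(0.2, 0.2, 0.2), 10), "sum to 1")
})

test_that("FRAP generator matches its closed form", {
  ## no recovery: post-bleach signal stays at bleach depth
  flat <- makeFrapTrace(plateau = 0, rate = 0.1, noiseSd = 0, seed = 1)
  post <- flat$trace@bleachRoi[flat$trace@bleachFrameIndex:
                                 length(flat$trace@times)]
  expect_true(all(post == 0))

  ## closed-form recovery, no bleaching or noise
  g <- makeFrapTrace(plateau = 0.8, rate = 0.1, acquisitionBleachRate = 0,
                     noiseSd = 0, frameInterval = 1, duration = 60, seed = 1)
  tr <- g$trace
  tp <- tr@times - tr@times[tr@bleachFrameIndex]
  expected <- ifelse(tp < 0, 1, 0.8 * (1 - exp(-0.1 * tp)))
  expect_equal(tr@bleachRoi, expected)

  ## acquisition bleaching: reference decays as exp(-lambda t)
  gb <- makeFrapTrace(plateau = 0.5, rate = 0.1,
                      acquisitionBleachRate = 0.01, noiseSd = 0,
                      frameInterval = 1, duration = 100, seed = 1)
  ref100 <- gb$trace@referenceRoi[gb$trace@times == 100]
  expect_equal(ref100, exp(-1))

  expect_error(makeFrapTrace(plateau = 1.2, rate = 0.1), "\\[0, 1\\]")
})

test_that("sensorgram generator produces the dilution series and reduces to
           the forward model", {
  p <- BivalentParams(1e5, 5e-3, 1e-3, 1e-3, 100)
  gen <- makeSensorgramSet(p, topConcentration = 256e-9, nDilutions = 6,
                           noiseSd = 0, seed = 1)
  expect_equal(gen$concentrations, 256e-9 / 2^(0:5))
  expect_equal(tail(gen$concentrations, 1), 8e-9)

  ## zero noise: identical to simulateBivalent
  grid <- seq(0, 360)
  direct <- simulateBivalent(p, 256e-9, grid)
  expect_equal(response(gen$sensorgrams[[1]]), response(direct))

  expect_error(makeSensorgramSet(p, topConcentration = -1), "positive")
  expect_error(makeSensorgramSet(p, topConcentration = 1e-9,
                                 dilutionFactor = 1), "> 1")
})

test_that("particle field conserves intensity and is reproducible", {
  empty <- makeParticleField(0, imageSize = 64, backgroundLevel = 5,
                             noiseSd = 0, seed = 1)
  expect_equal(sum(empty$image), 5 * 64 * 64)
  expect_equal(nrow(empty$truth), 0L)

  one <- makeParticleField(1, intensityMean = 800, intensitySd = 0,
                           imageSize = 64, backgroundLevel = 5, noiseSd = 0,
                           seed = 2)
  expect_equal(sum(one$image) - 5 * 64 * 64, 800, tolerance = 0.01)

  multi <- makeParticleField(8, imageSize = 128, noiseSd = 0, seed = 3)
  expect_equal(sum(multi$image) - 10 * 128 * 128,
               sum(multi$truth$intensity), tolerance = 0.01)

  again <- makeParticleField(8, imageSize = 128, noiseSd = 0, seed = 3)
  expect_identical(multi$image, again$image)

  crowded <- makeParticleField(40, imageSize = 48, psfSigma = 2, seed = 4)
  expect_true(crowded$crowded)
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(makeFrapTrace(plateau = 0.5, rate = 0.1, noiseSd = 0.1,
                          seed = 99))
  invisible(makeParticleField(3, seed = 42))
  expect_identical(.Random.seed, before)
})
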