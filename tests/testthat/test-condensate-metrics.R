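test_that("maxProject takes pixelwise maxima and preserves metadata", {
  a <- matrix(0, 4, 4); a[1, 1] <- 5
  b <- matrix(0, 4, 4); b[4, 4] <- 7
  proj <- maxProject(list(a, b))
  expect_equal(intensities(proj)[1, 1], 5)
  expect_equal(intensities(proj)[4, 4], 7)
  expect_equal(sum(intensities(proj)), 12)

  one <- NucleusImage(matrix(runif(16), 4, 4), pixelSize = 0.2,
                      channel = "mCherry")
  expect_identical(intensities(maxProject(list(one))), intensities(one))
  expect_equal(pixelSize(maxProject(list(one))), 0.2)

  zeros <- matrix(0, 3, 3); ones <- matrix(1, 3, 3)
  expect_true(all(intensities(maxProject(list(zeros, ones))) == 1))
  expect_error(maxProject(list(a, matrix(0, 3, 3))), "identical dimensions")
})

test_that("SCI matches sort-and-average oracle on hand-built profiles", {
  expect_equal(spatialClusteringIndex(rep(20, 100)), 1.0)

  prof <- c(rep(50, 5), rep(20, 90), rep(10, 5))
  expect_equal(spatialClusteringIndex(prof), 5.0)
  expect_equal(spatialClusteringIndex(prof), bruteForceSci(prof))

  prof20 <- c(40, rep(20, 18), 4)
  expect_equal(spatialClusteringIndex(prof20), 10.0)

  expect_error(spatialClusteringIndex(c(rep(0, 5), rep(1, 95))),
               "degenerate background")
  expect_error(spatialClusteringIndex(1:10), "at least 20")
})

test_that("SCI is scale invariant and shifts toward 1 under offsets", {
  set.seed(42)
  for (i in 1:10) {
    v <- rlnorm(60, 3, 0.5)
    s0 <- spatialClusteringIndex(v)
    expect_equal(spatialClusteringIndex(3.7 * v), s0)
    offsets <- c(5, 20, 80)
    scis <- vapply(offsets, function(c_) spatialClusteringIndex(v + c_),
                   numeric(1))
    expect_true(all(diff(c(s0, scis)) < 0))
    expect_true(all(scis >= 1))
  }
})

test_that("signal variance equals the direct (SD/mean)^2 formula", {
  m <- matrix(c(1, 3), 5, 10)          # multiset {1,3}, mean 2, pop SD 1
  expect_equal(as.numeric(nucleusSignalVariance(m, method = "whole")), 0.25)

  const <- matrix(7, 10, 10)
  expect_equal(as.numeric(nucleusSignalVariance(const, method = "whole")), 0)

  set.seed(7)
  r <- matrix(rlnorm(400, 2, 0.4), 20, 20)
  v <- as.numeric(nucleusSignalVariance(r, method = "whole"))
  expect_equal(v, directSignalVariance(as.vector(r)))
  expect_equal(as.numeric(nucleusSignalVariance(5 * r, method = "whole")), v)

  expect_error(nucleusSignalVariance(matrix(1, 3, 3), method = "whole",
                                     minForeground = 25L),
               "foreground pixels")
})

test_that("foreground variance selects the nucleus and matches the direct
           formula over the selected pixels", {
  g <- makeNucleusImage("spherical", seed = 11)
  v <- nucleusSignalVariance(g$image)
  fg <- attr(v, "foreground")
  expect_equal(as.numeric(v), directSignalVariance(intensities(g$image)[fg]))
  ## the selected particle is essentially the nucleus footprint
  msk <- nucleusMask(g$image)
  expect_gt(sum(fg & msk) / sum(msk), 0.9)
  expect_lt(sum(fg & !msk) / sum(fg), 0.05)
})

test_that("assembly classification applies the 0.21/0.45 cutoffs exactly", {
  expect_equal(as.character(classifyAssembly(0.10)), "diffuse")
  expect_equal(as.character(classifyAssembly(0.30)), "spherical")
  expect_equal(as.character(classifyAssembly(0.60)), "aggregate")
  ## boundary values belong to the closed middle bin
  expect_equal(as.character(classifyAssembly(c(0.21, 0.45))),
               c("spherical", "spherical"))
  expect_equal(as.character(classifyAssembly(0.21 - 1e-9)), "diffuse")
  expect_equal(as.character(classifyAssembly(0.45 + 1e-9)), "aggregate")
  expect_error(classifyAssembly(-0.1), "non-negative")
})

test_that("population fractions tally classifications", {
  cls <- classifyAssembly(c(0.1, 0.3, 0.6))
  pf <- populationFractions(cls)
  expect_equal(unname(pf$fractions), rep(1 / 3, 3))
  expect_equal(sum(pf$counts), 3L)

  allDiff <- populationFractions(rep("diffuse", 5))
  expect_equal(unname(allDiff$fractions), c(1, 0, 0))
  expect_error(populationFractions(character(0)), "empty")
})

test_that("mixture fit: k = 1 closed form, component recovery, and
           monotone EM log-likelihood", {
  set.seed(3)
  x <- rlnorm(100, -1, 0.4)
  f1 <- fitVarianceMixture(x, k = 1)
  expect_equal(f1$means, mean(x))
  expect_equal(f1$sds, sqrt(mean((x - mean(x))^2)))

  ## three well-separated components with known weights
  set.seed(9)
  n <- 3000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))
  mus <- c(0.05, 0.35, 0.8); sig <- c(0.02, 0.05, 0.08)
  x3 <- rnorm(n, mus[comp], sig[comp])
  f3 <- fitVarianceMixture(x3, k = 3, seed = 1)
  expect_true(all(abs(f3$weights - c(0.2, 0.3, 0.5)) < 0.03))
  expect_true(all(abs(f3$means - mus) < 0.02))
  expect_true(all(diff(f3$means) > 0))
  expect_true(all(diff(f3$logLikTrace) > -1e-7))
  expect_equal(length(f3$boundaries), 2L)
  expect_true(all(f3$boundaries > mus[-3] & f3$boundaries < mus[-1]))

  ## independent oracle: mclust on the same data
  skip_if_not_installed("mclust")
  suppressMessages(requireNamespace("mclust"))
  mc <- withr::with_package("mclust",
    Mclust(x3, G = 3, modelNames = "V", verbose = FALSE))
  expect_equal(sort(f3$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(f3$logLik, mc$loglik, tolerance = 1e-3 * abs(mc$loglik))
})

test_that("identical mixture components are flagged degenerate", {
  x <- rep(0.3, 60)
  f <- fitVarianceMixture(x, k = 2, seed = 1)
  expect_true(f$degenerate)
  expect_error(fitVarianceMixture(rnorm(8), k = 2), "at least 5k")
})

test_that("line profiles sample a wide line with bilinear interpolation", {
  ## column-gradient image: intensity = x coordinate
  im <- matrix(rep(0:49, each = 50), 50, 50)
  img <- NucleusImage(im, pixelSize = 0.1)
  prof <- extractLineProfile(img, x0 = 5, y0 = 25, x1 = 44, y1 = 25,
                             widthUm = 0.3)
  expect_gte(length(prof@values), 20)
  ## along a horizontal line the profile reproduces the gradient
  expect_equal(prof@values, seq(5, 44), tolerance = 1e-8)
  ## SCI of a linear ramp: top tail ~44, bottom ~5
  expect_equal(spatialClusteringIndex(prof), 43.5 / 5.5, tolerance = 1e-6)
})
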