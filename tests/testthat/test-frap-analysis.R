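test_that("normalisation removes acquisition bleaching exactly", {
  g <- makeFrapTrace(plateau = 0.8, rate = 0.1, acquisitionBleachRate = 0.02,
                     noiseSd = 0, seed = 1)
  nf <- normalizeFrapTrace(g$trace)
  expected <- 0.8 * (1 - exp(-0.1 * nf$tPrime))
  expect_equal(nf$postValues, expected, tolerance = 1e-12)
  expect_equal(mean(nf$values[seq_len(g$trace@prebleachFrames)]), 1)
  expect_equal(nf$postValues[1], 0)
})

test_that("normalisation is idempotent and rejects degenerate traces", {
  ## already-normalised trace: reference identically 1
  tp <- 0:40
  vals <- c(rep(1, 5), 0.6 * (1 - exp(-0.2 * tp)))
  tr <- FrapTrace(seq_along(c(rep(1, 5), tp)) - 1, vals,
                  rep(1, length(vals)), prebleachFrames = 5L)
  nf <- normalizeFrapTrace(tr)
  expect_equal(nf$values, vals, tolerance = 1e-12)

  ## bleach identical to reference: no bleach event
  fade <- exp(-0.01 * (0:50))
  same <- FrapTrace(0:50, fade, fade, prebleachFrames = 5L)
  expect_error(normalizeFrapTrace(same), "no bleach event")

  neg <- FrapTrace(0:50, fade, c(fade[1:30], 0, fade[32:51]),
                   prebleachFrames = 5L)
  expect_error(normalizeFrapTrace(neg), "non-positive")
})

test_that("one-phase-decay fit recovers noiseless truth to < 0.1%", {
  tp <- 0:60
  y <- 0.8 * (1 - exp(-0.1 * tp))
  fit <- fitOnePhaseDecay(y, tp)
  expect_equal(fit$plateau, 0.8, tolerance = 1e-3)
  expect_equal(fit$rate, 0.1, tolerance = 1e-3)
  expect_equal(fit$tHalf, log(2) / fit$rate)
  expect_true(fit$valid)
  expect_lt(fit$rss, 1e-12)

  flat <- fitOnePhaseDecay(rep(0, 30), 0:29)
  expect_equal(flat$plateau, 0, tolerance = 1e-6)
  expect_false(flat$valid)

  expect_error(fitOnePhaseDecay(c(0, 0.5, 0.7), 0:2), "at least 8")
})

test_that("parameter recovery under noise stays within stated error", {
  nTraces <- 100
  errsP <- errsR <- numeric(nTraces)
  for (i in seq_len(nTraces)) {
    g <- makeFrapTrace(plateau = 0.8, rate = 0.1,
                       acquisitionBleachRate = 0.01, noiseSd = 0.02,
                       frameInterval = 1, duration = 60, seed = 1000 + i)
    fit <- fitOnePhaseDecay(normalizeFrapTrace(g$trace))
    errsP[i] <- abs(fit$plateau - 0.8)
    errsR[i] <- abs(fit$rate - 0.1) / 0.1
  }
  expect_lt(median(errsP), 0.03)
  expect_lt(median(errsR), 0.10)
})

test_that("mobility classification uses a closed lower bound at the cutoff", {
  expect_equal(as.character(classifyMobility(0.8)), "liquid")
  expect_equal(as.character(classifyMobility(0.05)), "slow_diffusive")
  expect_equal(as.character(classifyMobility(0.4)), "liquid")
  expect_equal(as.character(classifyMobility(0.4 - 1e-9)), "slow_diffusive")
  expect_equal(as.character(classifyMobility(0.5, plateauCutoff = 0.6)),
               "slow_diffusive")
})

test_that("population summary: pointwise moments and class fractions", {
  g <- makeFrapTrace(plateau = 0.7, rate = 0.15, noiseSd = 0, seed = 1)
  same <- summarizeFrapPopulation(list(g$trace, g$trace))
  expect_true(all(same$sd == 0))

  ## two traces with values {0, 1} at each post-bleach frame:
  ## population mean 0.5, population SD 0.5
  n <- 20
  t0 <- FrapTrace(0:(n - 1), c(rep(1, 5), rep(0, n - 5)), rep(1, n),
                  prebleachFrames = 5L)
  t1 <- FrapTrace(0:(n - 1), c(rep(1, 5), 0, rep(1, n - 6)), rep(1, n),
                  prebleachFrames = 5L)
  two <- summarizeFrapPopulation(list(t0, t1))
  lastFrame <- n
  expect_equal(two$mean[lastFrame], 0.5)
  expect_equal(two$sd[lastFrame], 0.5)

  gA <- makeFrapTrace(plateau = 0.8, rate = 0.1, noiseSd = 0, seed = 1)
  gB <- makeFrapTrace(plateau = 0.8, rate = 0.1, noiseSd = 0, seed = 2,
                      duration = 100)
  expect_error(summarizeFrapPopulation(list(gA$trace, gB$trace)),
               "common time grid")
  expect_error(summarizeFrapPopulation(list(gA$trace)), "at least 2")
})

test_that("two-class FRAP mixtures recover the realized class composition", {
  slowFrac <- 0.76
  n <- 50
  rep1 <- runFrapExperiment(slowFraction = slowFrac, n = n, seed = 7)
  slowHat <- unname(rep1$fractions["slow_diffusive"])
  realized <- mean(rep1$perTrace$trueClass == "slow_diffusive")
  ## the fitted mobility calls recover the realized mixture composition
  expect_lt(abs(slowHat - realized), 0.05)
  expect_gte(rep1$accuracy, 0.95)
  ## and the realized composition is a draw around the preset weight
  expect_lt(abs(realized - slowFrac),
            3 * sqrt(slowFrac * (1 - slowFrac) / n))
})
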