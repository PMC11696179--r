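test_that("bivalent forward model obeys its limits", {
  p <- BivalentParams(1e5, 5e-3, 1e-3, 1e-3, 100)
  grid <- seq(0, 360)

  zero <- simulateBivalent(p, 0, grid)
  expect_true(all(response(zero) == 0))

  ## ka2 = 0, long association: Langmuir equilibrium Rmax C / (C + Kd)
  p1 <- BivalentParams(1e5, 5e-3, 0, 0, 100)
  for (conc in c(10e-9, 50e-9, 200e-9)) {
    sg <- simulateBivalent(p1, conc, seq(0, 4000), phaseBoundary = 4000)
    expect_equal(tail(response(sg), 1), 100 * conc / (conc + 50e-9),
                 tolerance = 1e-4)
  }

  ## Kd invariance: doubling ka1 and kd1 leaves equilibrium unchanged
  p2 <- BivalentParams(2e5, 1e-2, 0, 0, 100)
  eq1 <- tail(response(simulateBivalent(p1, 50e-9, seq(0, 4000),
                                        phaseBoundary = 4000)), 1)
  eq2 <- tail(response(simulateBivalent(p2, 50e-9, seq(0, 4000),
                                        phaseBoundary = 4000)), 1)
  expect_equal(eq1, eq2, tolerance = 1e-4)
})

test_that("response stays within physical bounds and dissociation is
           monotone", {
  p <- BivalentParams(5e5, 1e-2, 5e-3, 2e-3, 80)
  for (conc in c(8e-9, 64e-9, 256e-9)) {
    sg <- simulateBivalent(p, conc, seq(0, 360))
    r <- response(sg)
    expect_true(all(r >= -1e-9))
    expect_true(all(r <= 80 * 2 + 1e-9))
    dis <- r[timePoints(sg) > 60]
    expect_true(all(diff(dis) <= 1e-9))
  }
})

test_that("first-order Kd is kd1/ka1", {
  expect_equal(firstOrderKd(BivalentParams(1e5, 5e-3, 1e-3, 1e-3, 100)),
               50e-9)
  expect_equal(firstOrderKd(BivalentParams(1e6, 2e-2, 1e-3, 1e-3, 100)),
               20e-9)
  expect_equal(firstOrderKd(BivalentParams(1e5, 0, 0, 0, 100)), 0)
  expect_error(firstOrderKd(BivalentParams(0, 1e-3, 0, 0, 100)), "ka1")
})

test_that("global fit recovers a noiseless dilution series to < 0.1%", {
  truth <- BivalentParams(1e5, 5e-3, 1e-3, 1e-3, 100)
  gen <- makeSensorgramSet(truth, topConcentration = 256e-9, nDilutions = 6,
                           noiseSd = 0, seed = 1)
  fit <- fitBivalent(gen$sensorgrams, init = truth, perturbFactor = log(2),
                     nStarts = 2, seed = 3)
  expect_equal(fit$params@ka1, 1e5, tolerance = 1e-3)
  expect_equal(fit$params@kd1, 5e-3, tolerance = 1e-3)
  expect_equal(fit$firstOrderKd, 50e-9, tolerance = 1e-3)
  expect_true(fit$converged)
})

test_that("a single concentration triggers the ill-conditioning warning", {
  truth <- BivalentParams(1e5, 5e-3, 1e-3, 1e-3, 100)
  one <- makeSensorgramSet(truth, topConcentration = 128e-9, nDilutions = 1,
                           noiseSd = 0, seed = 1)
  expect_warning(fitBivalent(one$sensorgrams, init = truth, nStarts = 1,
                             seed = 1),
                 "ill-conditioned")
})
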