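test_that("spot detection on blank and constructed fields", {
  blank <- matrix(10, 64, 64)
  expect_equal(nrow(detectSpots(blank)), 0L)

  ## one bright Gaussian spot, SNR ~ 20
  f1 <- makeParticleField(1, intensityMean = 2000, intensitySd = 0,
                          psfSigma = 1.5, imageSize = 64,
                          backgroundLevel = 10, noiseSd = 5, seed = 1)
  sp <- detectSpots(f1$image, sigmaExpected = 1.5)
  expect_equal(nrow(sp), 1L)
  expect_lt(sqrt((sp$x - f1$truth$x)^2 + (sp$y - f1$truth$y)^2), 0.5)

  ## two spots 6 sigma apart are resolved
  im <- matrix(0, 64, 64)
  cols <- matrix(rep(0:63, each = 64), 64, 64)
  rows <- matrix(rep(0:63, times = 64), 64, 64)
  addSpot <- function(im, x, y, I, s = 1.5) {
    im + I / (2 * pi * s^2) * exp(-((cols - x)^2 + (rows - y)^2) / (2 * s^2))
  }
  im <- addSpot(im, 25, 30, 1000)
  im <- addSpot(im, 34, 30, 1000)     # 9 px = 6 sigma apart
  sp2 <- detectSpots(im, sigmaExpected = 1.5, qualityThreshold = 1)
  expect_equal(nrow(sp2), 2L)
})

test_that("detection recall and precision >= 0.95 on seeded fields", {
  nFields <- 100
  tp <- fp <- fn <- 0
  for (s in seq_len(nFields)) {
    f <- makeParticleField(8, intensityMean = 1000, intensitySd = 100,
                           psfSigma = 1.5, imageSize = 96,
                           backgroundLevel = 10, noiseSd = 5, seed = s)
    sp <- detectSpots(f$image, sigmaExpected = 1.5)
    m <- colocalizeChannels(f$truth, sp, radiusPx = 2)
    tp <- tp + nrow(m$pairs)
    fn <- fn + nrow(f$truth) - nrow(m$pairs)
    fp <- fp + nrow(sp) - nrow(m$pairs)
  }
  expect_gte(tp / (tp + fn), 0.95)   # recall
  expect_gte(tp / (tp + fp), 0.95)   # precision
})

test_that("total spot intensity is conserved and linear", {
  zero <- matrix(0, 48, 48)
  v0 <- spotTotalIntensity(zero, 24, 24, radius = 5)
  expect_equal(as.numeric(v0), 0)

  f <- makeParticleField(1, intensityMean = 1500, intensitySd = 0,
                         psfSigma = 1.5, imageSize = 64,
                         backgroundLevel = 20, noiseSd = 0, seed = 3)
  v <- spotTotalIntensity(f$image, f$truth$x, f$truth$y, radius = 6)
  expect_equal(as.numeric(v), 1500, tolerance = 0.05)
  v2 <- spotTotalIntensity(2 * f$image, f$truth$x, f$truth$y, radius = 6)
  expect_equal(as.numeric(v2), 2 * as.numeric(v), tolerance = 1e-9)

  ## unbiased within 5% across background levels up to 50% of peak
  peak <- 1500 / (2 * pi * 1.5^2)
  for (bg in c(0, 0.2, 0.5) * peak) {
    fb <- makeParticleField(1, intensityMean = 1500, intensitySd = 0,
                            psfSigma = 1.5, imageSize = 64,
                            backgroundLevel = bg, noiseSd = 0, seed = 4)
    vb <- spotTotalIntensity(fb$image, fb$truth$x, fb$truth$y, radius = 6)
    expect_equal(as.numeric(vb), 1500, tolerance = 0.05)
  }
})

test_that("border-clipped spots are flagged and excluded by default", {
  f <- makeParticleField(1, intensityMean = 1000, intensitySd = 0,
                         imageSize = 64, backgroundLevel = 5, noiseSd = 0,
                         seed = 5)
  inSpot <- spotTotalIntensity(f$image, f$truth$x, f$truth$y, radius = 5)
  expect_false(attr(inSpot, "clipped"))
  edge <- spotTotalIntensity(f$image, 1, 1, radius = 5)
  expect_true(attr(edge, "clipped"))

  spots <- data.frame(x = c(f$truth$x, 1), y = c(f$truth$y, 1),
                      sigma = c(1.5, 1.5), quality = c(1, 1))
  q <- quantifySpots(f$image, spots, radiusFactor = 3)
  expect_equal(nrow(q), 1L)
  q2 <- quantifySpots(f$image, spots, radiusFactor = 3, keepClipped = TRUE)
  expect_equal(nrow(q2), 2L)
})

test_that("colocalization via mutual nearest neighbours", {
  a <- data.frame(x = c(10, 30, 50), y = c(10, 30, 50))
  same <- colocalizeChannels(a, a, radiusPx = 2)
  expect_equal(same$fraction, 1)
  expect_equal(nrow(same$pairs), 3L)

  b <- data.frame(x = a$x + 100, y = a$y)   # far away
  expect_equal(colocalizeChannels(a, b, radiusPx = 5)$fraction, 0)

  shifted <- data.frame(x = a$x + 1, y = a$y)  # shift = radius / 2
  expect_equal(colocalizeChannels(a, shifted, radiusPx = 2)$fraction, 1)
})
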