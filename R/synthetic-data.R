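## Seeded generators for every input the pipeline consumes: nucleus images in
## three assembly states, FRAP traces with acquisition photobleaching,
## dilution-series sensorgrams from the bivalent model, and sparse
## diffraction-limited particle fields. Each generator is a pure function of
## its arguments (seed included) and returns ground truth alongside the data.

## Morphology constants. The three morphologies are minimal shapes spanning
## the three signal-variance bins (< 0.21, 0.21-0.45, > 0.45); amplitude and
## area parameters were calibrated once against the foreground-variance
## classifier (see the methods vignette) so that each class lands in its bin
## for >= 95% of seeds.
.nucMorph <- list(
  diffuse   = list(base = 1.00, noise = 0.07),
  spherical = list(base = 0.90, noise = 0.06, ampLo = 3.1, ampHi = 3.4,
                   fociLo = 7L, fociHi = 8L),
  aggregate = list(base = 0.60, noise = 0.06, ampLo = 4, ampHi = 7,
                   blobLo = 1L, blobHi = 3L, discLo = 5L, discHi = 9L)
)

#' Generate a synthetic nucleus image
#'
#' Draws a single-nucleus fluorescence image in one of the three assembly
#' states. A `diffuse` nucleus is a smooth elliptical region of constant
#' intensity plus Gaussian read noise; a `spherical` nucleus adds a few small
#' bright Gaussian foci on a dimmer nucleoplasm; an `aggregate` nucleus
#' carries 1-3 large irregular high-contrast blobs (unions of overlapping
#' discs of varying brightness) on a dim nucleoplasm. The noise model is
#' additive Gaussian; intensity units are arbitrary.
#'
#' @param assemblyClass `"diffuse"`, `"spherical"` or `"aggregate"`.
#' @param imageSize side of the square image, pixels.
#' @param pixelSize micrometres per pixel.
#' @param meanIntensity nucleoplasm reference intensity (arbitrary units > 0).
#' @param focusCount number of foci/blobs; `NULL` draws a class-typical count.
#'   Must be 0 for (and only for) the diffuse class.
#' @param focusRadius focus radius, micrometres (spherical class).
#' @param noiseSd read-noise SD as a fraction of `meanIntensity`; `NULL` uses
#'   the class default.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @return A list with `image` (a [NucleusImage-class] with the nucleus mask
#'   attached), `label` (the ground-truth class) and `seed`.
#' @examples
#' g <- makeNucleusImage("diffuse", seed = 1)
#' g$label
#' @export
makeNucleusImage <- function(assemblyClass = c("diffuse", "spherical",
                                               "aggregate"),
                             imageSize = 96L, pixelSize = 0.1,
                             meanIntensity = 100, focusCount = NULL,
                             focusRadius = 0.25, noiseSd = NULL, seed = 1L) {
  assemblyClass <- match.arg(assemblyClass)
  if (meanIntensity <= 0) stop("meanIntensity must be positive")
  mo <- .nucMorph[[assemblyClass]]
  if (is.null(noiseSd)) noiseSd <- mo$noise
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!is.null(focusCount)) {
    if ((focusCount == 0L) != (assemblyClass == "diffuse")) {
      stop("focusCount must be 0 if and only if assemblyClass is 'diffuse'")
    }
  }
  .withSeed(seed, {
    n <- as.integer(imageSize)
    cx <- (n + 1) / 2; cy <- (n + 1) / 2
    rx <- 0.22 * n * runif(1, 0.95, 1.05)
    ry <- 0.18 * n * runif(1, 0.95, 1.05)
    th <- runif(1, 0, pi)
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    mask <- (xr / rx)^2 + (yr / ry)^2 <= 1
    sigmaPx <- focusRadius / pixelSize
    im <- matrix(0, n, n)
    im[mask] <- mo$base * meanIntensity
    addGaussian <- function(im, x0, y0, sigma, amp) {
      d2 <- (xs - x0)^2 + (ys - y0)^2
      im + amp * exp(-d2 / (2 * sigma^2))
    }
    randInside <- function(shrink = 0.7) {
      repeat {
        u <- runif(1, -shrink, shrink); v <- runif(1, -shrink, shrink)
        if (u^2 + v^2 <= shrink^2) {
          x <- cx + u * rx * cos(th) - v * ry * sin(th)
          y <- cy + u * rx * sin(th) + v * ry * cos(th)
          return(c(x, y))
        }
      }
    }
    if (assemblyClass == "spherical") {
      k <- if (is.null(focusCount)) sample(mo$fociLo:mo$fociHi, 1L)
           else as.integer(focusCount)
      if (k * pi * (2 * sigmaPx)^2 > 0.9 * sum(mask)) {
        stop("image too small to place ", k, " foci")
      }
      placedX <- numeric(0); placedY <- numeric(0)
      for (i in seq_len(k)) {
        ## keep foci apart so overlaps do not inflate the variance
        for (att in 1:50) {
          p <- randInside(0.75)
          if (length(placedX) == 0L ||
              min((placedX - p[1])^2 + (placedY - p[2])^2) >=
                (3.5 * sigmaPx)^2) break
        }
        placedX <- c(placedX, p[1]); placedY <- c(placedY, p[2])
        amp <- runif(1, mo$ampLo, mo$ampHi) * meanIntensity
        im <- addGaussian(im, p[1], p[2], sigmaPx * runif(1, 0.95, 1.1), amp)
      }
    } else if (assemblyClass == "aggregate") {
      k <- if (is.null(focusCount)) sample(mo$blobLo:mo$blobHi, 1L)
           else as.integer(focusCount)
      if (k > 6L) stop("image too small to place ", k, " blobs")
      for (i in seq_len(k)) {
        centre <- randInside(0.55)
        nd <- sample(mo$discLo:mo$discHi, 1L)
        for (j in seq_len(nd)) {
          off <- rnorm(2, 0, 0.05 * n)
          r <- runif(1, 0.03, 0.07) * n
          amp <- exp(runif(1, log(mo$ampLo), log(mo$ampHi))) * meanIntensity
          d2 <- (xs - centre[1] - off[1])^2 + (ys - centre[2] - off[2])^2
          im <- im + amp * exp(-(d2 / (2 * r^2))^2)   # flat-top disc-like
        }
      }
    }
    im[mask] <- im[mask] + rnorm(sum(mask), 0, noiseSd * meanIntensity)
    im[!mask] <- abs(rnorm(sum(!mask), 0, 0.01 * meanIntensity))
    im[im < 0] <- 0
    list(image = NucleusImage(im, pixelSize = pixelSize, mask = mask),
         label = assemblyClass, seed = as.integer(seed))
  })
}

#' Generate a population of synthetic nuclei
#'
#' Draws `n` ground-truth labels from a multinomial distribution over the
#' three assembly states and generates one nucleus image per label with
#' per-image child seeds.
#'
#' @param weights length-3 non-negative weights over
#'   (diffuse, spherical, aggregate), summing to 1.
#' @param n number of nuclei.
#' @param seed integer seed.
#' @param ... further arguments passed to [makeNucleusImage()].
#' @return A list with `images` (list of [NucleusImage-class]), `labels`
#'   (ground-truth factor) and `truth` (data frame with id, class, seed).
#' @examples
#' pop <- makeNucleusPopulation(c(0.16, 0.36, 0.48), n = 5, seed = 1)
#' table(pop$labels)
#' @export
makeNucleusPopulation <- function(weights, n, seed = 1L, ...) {
  weights <- as.numeric(weights)
  if (length(weights) != 3L) stop("weights must have length 3")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  if (n < 1L) stop("n must be >= 1")
  labels <- .withSeed(seed, {
    sample(assemblyClasses(), n, replace = TRUE, prob = weights)
  })
  images <- vector("list", n)
  for (i in seq_len(n)) {
    g <- makeNucleusImage(labels[i], seed = .childSeed(seed, i), ...)
    images[[i]] <- g$image
  }
  list(images = images,
       labels = factor(labels, levels = assemblyClasses()),
       truth = data.frame(id = seq_len(n), class = labels,
                          seed = vapply(seq_len(n), function(i)
                            .childSeed(seed, i), integer(1))))
}

#' Generate a synthetic FRAP trace
#'
#' Simulates a bleach-ROI / reference-ROI pair. Before the bleach pulse both
#' ROIs sit at normalised intensity 1; after the pulse the bleach ROI follows
#' the one-phase recovery `plateau * (1 - exp(-rate * t'))` (t' = time since
#' bleach; full bleach to 0 at t' = 0). Both ROIs are multiplied by the
#' acquisition-photobleaching factor `exp(-acquisitionBleachRate * t)` (t =
#' time since acquisition start) and carry additive Gaussian noise.
#'
#' @param plateau recovery plateau (mobile fraction proxy), in `[0, 1]`.
#' @param rate recovery rate, 1/s.
#' @param acquisitionBleachRate photobleaching rate during acquisition, 1/s.
#' @param noiseSd additive noise SD (fraction of prebleach intensity).
#' @param frameInterval seconds between frames.
#' @param duration post-bleach duration, s.
#' @param prebleachFrames number of prebleach frames (>= 1).
#' @param seed integer seed.
#' @return A list with `trace` (a [FrapTrace-class]) and `truth` (the
#'   generating parameters).
#' @examples
#' tr <- makeFrapTrace(plateau = 0.8, rate = 0.1, seed = 1)
#' tr$truth$plateau
#' @export
makeFrapTrace <- function(plateau, rate, acquisitionBleachRate = 0,
                          noiseSd = 0, frameInterval = 1, duration = 60,
                          prebleachFrames = 5L, seed = 1L) {
  if (plateau < 0 || plateau > 1) stop("plateau must be in [0, 1]")
  if (duration <= 0 || frameInterval <= 0) {
    stop("duration and frameInterval must be positive")
  }
  if (acquisitionBleachRate < 0 || noiseSd < 0) {
    stop("acquisitionBleachRate and noiseSd must be >= 0")
  }
  prebleachFrames <- as.integer(prebleachFrames)
  if (prebleachFrames < 1L) stop("prebleachFrames must be >= 1")
  nPost <- floor(duration / frameInterval) + 1L
  times <- seq(0, by = frameInterval,
               length.out = prebleachFrames + nPost)
  tBleach <- times[prebleachFrames + 1L]
  tPrime <- pmax(times - tBleach, 0)
  recovery <- c(rep(1, prebleachFrames),
                plateau * (1 - exp(-rate * tPrime[-seq_len(prebleachFrames)])))
  fade <- exp(-acquisitionBleachRate * times)
  .withSeed(seed, {
    bleach <- recovery * fade + rnorm(length(times), 0, noiseSd)
    ref <- fade + rnorm(length(times), 0, noiseSd)
    trace <- FrapTrace(times, bleach, ref,
                       prebleachFrames = prebleachFrames,
                       bleachFrameIndex = prebleachFrames + 1L)
    list(trace = trace,
         truth = list(plateau = plateau, rate = rate,
                      acquisitionBleachRate = acquisitionBleachRate,
                      noiseSd = noiseSd, seed = as.integer(seed)))
  })
}

#' Generate a dilution-series set of synthetic sensorgrams
#'
#' Simulates one sensorgram per concentration of a geometric (default
#' two-fold) dilution series from the bivalent analyte model, with optional
#' additive and/or multiplicative Gaussian noise. With zero noise the output
#' is identical to [simulateBivalent()].
#'
#' @param params a [BivalentParams-class] (ground truth).
#' @param topConcentration highest analyte concentration, molar.
#' @param dilutionFactor dilution factor between consecutive concentrations
#'   (> 1; default 2).
#' @param nDilutions number of concentrations (>= 1).
#' @param associationTime injection length, s (default 60).
#' @param dissociationTime dissociation-phase length, s (default 300).
#' @param noiseSd additive noise SD, RU.
#' @param relNoiseSd multiplicative noise SD (fraction of the response).
#' @param dt sensorgram sampling interval, s.
#' @param seed integer seed.
#' @return A list with `sensorgrams` (list of [Sensorgram-class]),
#'   `concentrations` and `truth` (the generating parameters).
#' @export
makeSensorgramSet <- function(params, topConcentration, dilutionFactor = 2,
                              nDilutions = 6L, associationTime = 60,
                              dissociationTime = 300, noiseSd = 0,
                              relNoiseSd = 0, dt = 1, seed = 1L) {
  stopifnot(is(params, "BivalentParams"))
  if (topConcentration <= 0) stop("topConcentration must be positive")
  if (dilutionFactor <= 1) stop("dilutionFactor must be > 1")
  if (nDilutions < 1L) stop("nDilutions must be >= 1")
  conc <- topConcentration / dilutionFactor^(seq_len(nDilutions) - 1)
  grid <- seq(0, associationTime + dissociationTime, by = dt)
  clean <- lapply(conc, function(cc) {
    simulateBivalent(params, cc, grid, phaseBoundary = associationTime)
  })
  .withSeed(seed, {
    noisy <- lapply(clean, function(sg) {
      r <- response(sg)
      r <- r * (1 + rnorm(length(r), 0, relNoiseSd)) +
        rnorm(length(r), 0, noiseSd)
      Sensorgram(timePoints(sg), r, sg@analyteConcentration,
                 phaseBoundary = sg@phaseBoundary)
    })
    list(sensorgrams = noisy, concentrations = conc,
         truth = list(params = params, noiseSd = noiseSd,
                      relNoiseSd = relNoiseSd, seed = as.integer(seed)))
  })
}

#' Generate a sparse diffraction-limited particle field
#'
#' Places `nSpots` 2-D Gaussian spots of given integrated intensity on a flat
#' background with additive Gaussian noise, emulating a TIRF single-particle
#' field. The truth table records sub-pixel positions and total intensities;
#' when spots could not be placed with the requested minimum separation the
#' field is flagged as crowded.
#'
#' @param nSpots number of spots (>= 0).
#' @param intensityMean mean integrated spot intensity (arbitrary units).
#' @param intensitySd SD of integrated spot intensities.
#' @param psfSigma Gaussian PSF sigma, pixels.
#' @param imageSize side of the square image, pixels.
#' @param backgroundLevel flat background level.
#' @param noiseSd additive noise SD.
#' @param minSeparation minimum centre-to-centre spot distance, pixels.
#' @param seed integer seed.
#' @return A list with `image` (numeric matrix), `truth` (data frame: x, y,
#'   sigma, intensity; 0-based sub-pixel coordinates) and `crowded` flag.
#' @export
makeParticleField <- function(nSpots, intensityMean = 500, intensitySd = 50,
                              psfSigma = 1.5, imageSize = 128L,
                              backgroundLevel = 10, noiseSd = 2,
                              minSeparation = 6 * psfSigma, seed = 1L) {
  if (nSpots < 0L) stop("nSpots must be >= 0")
  n <- as.integer(imageSize)
  .withSeed(seed, {
    margin <- ceiling(4 * psfSigma)
    xs <- numeric(0); ys <- numeric(0)
    crowded <- FALSE
    for (i in seq_len(nSpots)) {
      placed <- FALSE
      for (att in seq_len(200L)) {
        x <- runif(1, margin, n - 1 - margin)
        y <- runif(1, margin, n - 1 - margin)
        if (length(xs) == 0L ||
            min((xs - x)^2 + (ys - y)^2) >= minSeparation^2) {
          placed <- TRUE
          break
        }
      }
      if (!placed) crowded <- TRUE   # keep the last draw, flag the field
      xs <- c(xs, x); ys <- c(ys, y)
    }
    ints <- if (nSpots > 0L) pmax(rnorm(nSpots, intensityMean, intensitySd),
                                  0.1 * intensityMean) else numeric(0)
    cols <- matrix(rep(0:(n - 1), each = n), n, n)
    rows <- matrix(rep(0:(n - 1), times = n), n, n)
    im <- matrix(backgroundLevel, n, n)
    for (i in seq_len(nSpots)) {
      amp <- ints[i] / (2 * pi * psfSigma^2)
      im <- im + amp * exp(-((cols - xs[i])^2 + (rows - ys[i])^2) /
                             (2 * psfSigma^2))
    }
    im <- im + rnorm(n * n, 0, noiseSd)
    im[im < 0] <- 0
    list(image = im,
         truth = data.frame(x = xs, y = ys,
                            sigma = rep(psfSigma, nSpots),
                            intensity = ints),
         crowded = crowded)
  })
}
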