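## Clustering statistics on nuclear images: maximum projection, line-profile
## spatial clustering index (SCI), per-nucleus signal variance, three-state
## assembly classification, and Gaussian mixture fitting of variance
## distributions.

#' Maximum-intensity projection of a z-stack
#'
#' Collapses a list of image planes into a single plane by taking, for every
#' pixel, the maximum intensity across planes (the projection applied to
#' z-stacks before clustering analysis).
#'
#' @param stack a list of [NucleusImage-class] objects or numeric matrices,
#'   all with identical dimensions, or a 3-D array (rows x cols x planes).
#' @return A [NucleusImage-class] whose pixels are the per-pixel maxima.
#'   Pixel size, channel and mask are taken from the first plane when the
#'   input is a list of `NucleusImage` objects.
#' @examples
#' a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
#' a[1, 1] <- 5; b[4, 4] <- 7
#' intensities(maxProject(list(a, b)))[c(1, 16)]
#' @export
maxProject <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  }
  if (!is.list(stack) || length(stack) < 1L) {
    stop("'stack' must contain at least one plane")
  }
  first <- stack[[1L]]
  template <- if (is(first, "NucleusImage")) first else NULL
  mats <- lapply(stack, function(p) {
    if (is(p, "NucleusImage")) intensities(p) else as.matrix(p)
  })
  d <- dim(mats[[1L]])
  ok <- vapply(mats, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all planes must have identical dimensions")
  proj <- Reduce(pmax, mats)
  if (!is.null(template)) {
    NucleusImage(proj, pixelSize = pixelSize(template),
                 channel = template@channel, mask = nucleusMask(template))
  } else {
    NucleusImage(proj)
  }
}

#' Spatial clustering index of a line profile
#'
#' The SCI of an intensity profile is the ratio of the mean of the top 5% of
#' values to the mean of the bottom 5% of values. A perfectly uniform signal
#' gives 1; clustering of signal into foci raises the ratio.
#'
#' Tails have size `max(1, floor(tailFraction * n))`; ties are broken by the
#' stable sort order of the values.
#'
#' @param profile a [LineProfile-class] or a numeric vector of intensities.
#' @param tailFraction fraction of values in each tail (default 0.05).
#' @return A single numeric SCI value (>= 1 for non-degenerate profiles).
#' @examples
#' spatialClusteringIndex(c(rep(50, 5), rep(20, 90), rep(10, 5)))  # 5
#' @export
spatialClusteringIndex <- function(profile, tailFraction = 0.05) {
  v <- if (is(profile, "LineProfile")) profile@values else as.numeric(profile)
  n <- length(v)
  if (n < ceiling(1 / tailFraction)) {
    stop("profile must have at least ", ceiling(1 / tailFraction), " values")
  }
  m <- max(1L, floor(tailFraction * n))
  srt <- sort(v, method = "radix")   # stable
  lo <- mean(srt[seq_len(m)])
  hi <- mean(srt[seq.int(n - m + 1L, n)])
  if (lo <= 0) stop("degenerate background: bottom-tail mean is not positive")
  hi / lo
}

#' Extract a wide line profile from a nucleus image
#'
#' Samples intensities by bilinear interpolation at pixel pitch along a line
#' from `(x0, y0)` to `(x1, y1)` (0-based coordinates, pixel centres at
#' integers), averaging across the line width perpendicular to its axis.
#' The default 3 um width matches the ROI convention used for nuclear
#' cluster-index analysis.
#'
#' @param image a [NucleusImage-class].
#' @param x0,y0,x1,y1 line end points in 0-based pixel coordinates
#'   (x = column, y = row).
#' @param widthUm line width in micrometres (default 3).
#' @param source optional id recorded in the profile.
#' @return A [LineProfile-class].
#' @export
extractLineProfile <- function(image, x0, y0, x1, y1, widthUm = 3,
                               source = NA_character_) {
  stopifnot(is(image, "NucleusImage"))
  im <- intensities(image)
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) stop("line has zero length")
  d <- c(x1 - x0, y1 - y0) / len
  nrm <- c(-d[2], d[1])
  widthPx <- widthUm / pixelSize(image)
  offsets <- seq(-widthPx / 2, widthPx / 2, by = 1)
  along <- seq(0, len, by = 1)
  vals <- vapply(along, function(t) {
    xs <- x0 + t * d[1] + offsets * nrm[1]
    ys <- y0 + t * d[2] + offsets * nrm[2]
    v <- .bilinear(im, xs, ys)
    mean(v, na.rm = TRUE)
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  LineProfile(vals, lineWidth = widthUm, source = source)
}

## bilinear interpolation at 0-based (x = col, y = row) coordinates;
## NA outside the image
.bilinear <- function(im, xs, ys) {
  nr <- nrow(im); nc <- ncol(im)
  x0i <- floor(xs); y0i <- floor(ys)
  fx <- xs - x0i; fy <- ys - y0i
  get <- function(r, c) {
    out <- rep(NA_real_, length(r))
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    out[ok] <- im[cbind(r[ok] + 1L, c[ok] + 1L)]
    out
  }
  v00 <- get(y0i, x0i);     v01 <- get(y0i, x0i + 1)
  v10 <- get(y0i + 1, x0i); v11 <- get(y0i + 1, x0i + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Per-nucleus signal variance
#'
#' Computes the signal variance statistic `(SD / mean)^2` of pixel
#' intensities, the scalar used to classify nuclear assembly state. By
#' default the statistic is computed over a thresholded foreground standing
#' in for interactive particle selection: Otsu's threshold is computed on
#' log-transformed intensities of the nucleus region (the mask when present,
#' otherwise the whole image), connected components smaller than
#' `minComponent` pixels are discarded, and the variance is computed over
#' the original intensities of the selected region. Thresholding on the log
#' scale separates signal from the dark background (fluorescence intensity
#' histograms are approximately log-normal) instead of latching onto the
#' brightest foci, so the selected particle is the nucleus footprint.
#' `method = "whole"` instead uses every pixel of the nucleus region.
#'
#' The SD convention is the population SD (divide by n). The statistic is
#' invariant to rescaling all intensities by a positive constant.
#'
#' @param image a [NucleusImage-class] or a numeric matrix.
#' @param method `"foreground"` (default) or `"whole"`.
#' @param minComponent minimum connected-component size kept (pixels).
#' @param minForeground minimum number of foreground pixels required.
#' @return A single numeric variance with attribute `"foreground"`: the
#'   logical pixel mask the statistic was computed over.
#' @examples
#' m <- matrix(c(1, 3), 5, 10)
#' nucleusSignalVariance(m, method = "whole")  # 0.25
#' @export
nucleusSignalVariance <- function(image, method = c("foreground", "whole"),
                                  minComponent = 4L, minForeground = 25L) {
  method <- match.arg(method)
  if (is(image, "NucleusImage")) {
    im <- intensities(image)
    msk <- nucleusMask(image)
  } else {
    im <- as.matrix(image)
    msk <- NULL
  }
  region <- if (is.null(msk)) matrix(TRUE, nrow(im), ncol(im)) else msk
  if (method == "whole") {
    fg <- region
  } else {
    rng <- range(im)                 # threshold signal against background
    if (diff(rng) <= 0) {
      fg <- region                       # constant image: keep everything
    } else {
      lg <- log1p(im - rng[1])
      scaled <- lg / max(lg)
      thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
      bin <- scaled > thr & region
      lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
      labm <- EBImage::imageData(lab)
      if (max(labm) > 0) {
        keep <- which(tabulate(labm[labm > 0]) >= minComponent)
        fg <- matrix(labm %in% keep, nrow(im), ncol(im))
      } else {
        fg <- matrix(FALSE, nrow(im), ncol(im))
      }
    }
  }
  v <- im[fg]
  if (length(v) == 0L) stop("empty foreground after thresholding")
  if (length(v) < minForeground) {
    stop("only ", length(v), " foreground pixels (need >= ", minForeground, ")")
  }
  mu <- mean(v)
  if (mu == 0) stop("zero mean intensity in foreground")
  sdp <- sqrt(mean((v - mu)^2))          # population SD
  out <- (sdp / mu)^2
  attr(out, "foreground") <- fg
  out
}

#' Classify assembly state from signal variance
#'
#' Maps signal-variance values onto the three assembly states of nuclear
#' condensates: `diffuse` (variance < 0.21), `spherical` condensate
#' (0.21-0.45, boundaries inclusive) and irreversible `aggregate`
#' (variance > 0.45).
#'
#' @param variance numeric vector of non-negative signal variances.
#' @param thresholds length-2 numeric `(t_low, t_high)`, default
#'   `c(0.21, 0.45)`.
#' @return A factor with levels `diffuse`, `spherical`, `aggregate`.
#' @examples
#' classifyAssembly(c(0.10, 0.30, 0.60))
#' @export
classifyAssembly <- function(variance, thresholds = c(0.21, 0.45)) {
  variance <- as.numeric(variance)
  if (any(!is.finite(variance)) || any(variance < 0)) {
    stop("variance must be finite and non-negative")
  }
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  cls <- ifelse(variance < thresholds[1], "diffuse",
         ifelse(variance <= thresholds[2], "spherical", "aggregate"))
  factor(cls, levels = assemblyClasses())
}

#' The three assembly states
#' @return `c("diffuse", "spherical", "aggregate")`
#' @export
assemblyClasses <- function() c("diffuse", "spherical", "aggregate")

#' Fit a Gaussian mixture to signal-variance values
#'
#' Maximum-likelihood univariate Gaussian mixture fitted by
#' expectation-maximisation with seeded multi-start, the model behind
#' multipeak fitting of signal-variance distributions. Components are
#' reported in ascending mean order, together with the crossing points of
#' adjacent weighted component densities (the data-driven class boundaries).
#'
#' @param x numeric vector of variances (length >= 5k).
#' @param k number of components (default 3).
#' @param nRestarts number of seeded EM restarts (default 10).
#' @param seed RNG seed for the restarts.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations per restart.
#' @return A list of class `"VarianceMixtureFit"` with elements `k`,
#'   `weights`, `means`, `sds`, `logLik`, `logLikTrace` (per-iteration
#'   log-likelihood of the best restart), `boundaries` (k-1 crossing points,
#'   NA where adjacent components do not cross), `degenerate` (TRUE when two
#'   components coincide and weights are non-identifiable), and `converged`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0.1, 0.03), rnorm(300, 0.8, 0.05))
#' fitVarianceMixture(x, k = 2)$means
#' @export
fitVarianceMixture <- function(x, k = 3L, nRestarts = 10L, seed = 1L,
                               tol = 1e-8, maxIter = 1000L) {
  x <- as.numeric(x)
  n <- length(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n < 5L * k) stop("need at least 5k observations (n = ", n, ", k = ",
                       k, ")")
  mu0 <- mean(x)
  sd0 <- sqrt(mean((x - mu0)^2))
  if (k == 1L) {
    ll <- sum(dnorm(x, mu0, max(sd0, 1e-12), log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu0, sds = sd0,
                          logLik = ll, logLikTrace = ll, boundaries = numeric(0),
                          degenerate = FALSE, converged = TRUE),
                     class = "VarianceMixtureFit"))
  }
  sdFloor <- max(1e-8 * max(sd0, 1), 1e-12)
  best <- NULL
  best <- .withSeed(seed, {
  for (r in seq_len(nRestarts)) {
    mu <- sort(sample(x, k, prob = NULL))
    sg <- rep(max(sd0 / k, sdFloor), k)
    w <- rep(1 / k, k)
    trace <- numeric(0)
    llOld <- -Inf
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      dens <- vapply(seq_len(k),
                     function(j) w[j] * dnorm(x, mu[j], sg[j]), numeric(n))
      rowS <- rowSums(dens)
      if (any(rowS <= 0) || any(!is.finite(rowS))) break
      ll <- sum(log(rowS))
      trace <- c(trace, ll)
      resp <- dens / rowS
      nk <- colSums(resp)
      if (any(nk < 1e-10)) break        # emptied component
      w <- nk / n
      mu <- colSums(resp * x) / nk
      sg <- sqrt(vapply(seq_len(k), function(j) {
        sum(resp[, j] * (x - mu[j])^2) / nk[j]
      }, numeric(1)))
      sg <- pmax(sg, sdFloor)
      if (is.finite(llOld) && abs(ll - llOld) < tol * (abs(llOld) + tol)) {
        conv <- TRUE
        break
      }
      llOld <- ll
    }
    if (length(trace) == 0L) next
    cand <- list(weights = w, means = mu, sds = sg,
                 logLik = trace[length(trace)], trace = trace,
                 converged = conv)
    if (is.null(best) || cand$logLik > best$logLik) best <- cand
  }
  best
  })
  if (is.null(best) || !best$converged) {
    stop("EM did not converge in any of ", nRestarts, " restarts",
         if (!is.null(best)) paste0(" (best log-likelihood ",
                                    format(best$logLik), ")") else "")
  }
  ord <- order(best$means)
  w <- best$weights[ord]; mu <- best$means[ord]; sg <- best$sds[ord]
  degenerate <- any(diff(mu) < 1e-6 * max(sd0, 1e-12) &
                    abs(diff(sg)) < 1e-6 * max(sd0, 1e-12))
  bounds <- vapply(seq_len(k - 1L), function(j) {
    f <- function(t) {
      log(w[j]) + dnorm(t, mu[j], sg[j], log = TRUE) -
        log(w[j + 1]) - dnorm(t, mu[j + 1], sg[j + 1], log = TRUE)
    }
    lo <- mu[j]; hi <- mu[j + 1]
    if (hi <= lo || !is.finite(f(lo)) || !is.finite(f(hi)) ||
        f(lo) * f(hi) > 0) return(NA_real_)
    uniroot(f, c(lo, hi))$root
  }, numeric(1))
  structure(list(k = k, weights = w, means = mu, sds = sg,
                 logLik = best$logLik, logLikTrace = best$trace,
                 boundaries = bounds, degenerate = degenerate,
                 converged = TRUE),
            class = "VarianceMixtureFit")
}

#' @export
print.VarianceMixtureFit <- function(x, ...) {
  cat("Gaussian mixture fit, k =", x$k, "\n")
  tab <- data.frame(weight = round(x$weights, 4),
                    mean = signif(x$means, 5), sd = signif(x$sds, 5))
  print(tab, row.names = FALSE)
  cat("log-likelihood:", format(x$logLik), "\n")
  if (length(x$boundaries)) {
    cat("boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  }
  if (x$degenerate) cat("warning: degenerate components (weights not identifiable)\n")
  invisible(x)
}

#' Class fractions of a population of nuclei
#'
#' Tallies assembly classifications into counts and fractions over the three
#' states.
#'
#' @param classifications a factor/character vector of assembly classes (as
#'   returned by [classifyAssembly()]).
#' @return A list with `fractions` (named 3-simplex) and `counts` (named
#'   integer vector summing to n).
#' @examples
#' populationFractions(classifyAssembly(c(0.1, 0.3, 0.6)))$fractions
#' @export
populationFractions <- function(classifications) {
  if (length(classifications) == 0L) stop("empty classification list")
  cls <- factor(as.character(classifications), levels = assemblyClasses())
  if (anyNA(cls)) stop("unknown assembly class label")
  counts <- table(cls)
  counts <- setNames(as.integer(counts), names(counts))
  list(fractions = counts / sum(counts), counts = counts)
}
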