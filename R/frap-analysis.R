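## FRAP analysis: reference-ROI normalisation of bleach traces, one-phase
## exponential recovery fitting, liquid vs slow-diffusive mobility calls, and
## population summaries.

#' Normalise a FRAP trace against its reference ROI
#'
#' Divides the bleach-ROI series by the reference-ROI series to remove
#' acquisition photobleaching, then applies full-scale normalisation: the
#' prebleach mean is rescaled to 1 and the first post-bleach frame to 0, so
#' the recovery plateau reads directly as a mobile-fraction proxy.
#'
#' @param trace a [FrapTrace-class].
#' @param minBleachDepth minimum relative drop at the bleach frame required
#'   to accept that a bleach event occurred (default 0.1).
#' @return A list of class `"FrapNormalized"` with `times`, `values`
#'   (normalised series over all frames), `tPrime` (time since bleach for the
#'   post-bleach frames), `postValues`, `prebleachFrames` and
#'   `bleachFrameIndex`.
#' @examples
#' tr <- makeFrapTrace(plateau = 0.8, rate = 0.1, seed = 1)$trace
#' nf <- normalizeFrapTrace(tr)
#' range(nf$postValues)
#' @export
normalizeFrapTrace <- function(trace, minBleachDepth = 0.1) {
  stopifnot(is(trace, "FrapTrace"))
  ref <- trace@referenceRoi
  if (any(ref <= 0)) stop("reference ROI contains non-positive frames")
  ratio <- trace@bleachRoi / ref
  pre <- seq_len(trace@prebleachFrames)
  b <- trace@bleachFrameIndex
  preMean <- mean(ratio[pre])
  depth <- preMean - ratio[b]
  if (!is.finite(depth) || depth < minBleachDepth * abs(preMean)) {
    stop("no bleach event detected: post-bleach frame is not below the ",
         "prebleach level")
  }
  values <- (ratio - ratio[b]) / depth
  post <- seq.int(b, length(ratio))
  structure(list(times = trace@times, values = values,
                 tPrime = trace@times[post] - trace@times[b],
                 postValues = values[post],
                 prebleachFrames = trace@prebleachFrames,
                 bleachFrameIndex = b),
            class = "FrapNormalized")
}

#' Fit a one-phase-decay recovery model
#'
#' Fits `F(t') = plateau * (1 - exp(-rate * t'))` to a normalised
#' post-bleach recovery by bounded nonlinear least squares (plateau in
#' `[0, 1.5]`, rate in `(0, 10]`; offset fixed at 0). Initial guesses are the
#' mean of the last quartile (plateau) and `ln(2) / t_halfmax` (rate).
#'
#' @param normalized a `"FrapNormalized"` object from [normalizeFrapTrace()],
#'   or a numeric vector of post-bleach recovery values.
#' @param times time points (seconds since bleach) when `normalized` is a
#'   plain numeric vector; ignored otherwise.
#' @param plateauCutoff mobility cutoff forwarded to [classifyMobility()].
#' @return A list of class `"FrapFit"`: `plateau`, `rate` (1/s), `tHalf`
#'   (`ln(2)/rate`), `baseline` (0), `rss`, `valid` (FALSE when the rate is
#'   unidentifiable, e.g. a flat trace), `mobilityClass`.
#' @examples
#' tp <- 0:60
#' fit <- fitOnePhaseDecay(0.8 * (1 - exp(-0.1 * tp)), tp)
#' c(fit$plateau, fit$rate)
#' @export
fitOnePhaseDecay <- function(normalized, times = NULL, plateauCutoff = 0.4) {
  if (inherits(normalized, "FrapNormalized")) {
    y <- normalized$postValues
    tp <- normalized$tPrime
  } else {
    y <- as.numeric(normalized)
    if (is.null(times)) stop("'times' is required for a plain numeric series")
    tp <- as.numeric(times) - times[1]
  }
  if (length(y) < 8L) stop("need at least 8 post-bleach frames")
  p0 <- mean(y[tp >= quantile(tp, 0.75)])
  p0 <- min(max(p0, 0.01), 1.4)
  halfIdx <- which(y >= p0 / 2)
  tHalf0 <- if (length(halfIdx)) max(tp[halfIdx[1]], tp[2] / 2) else
    max(tp) / 5
  r0 <- min(max(log(2) / tHalf0, 1e-3), 9)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ plateau * (1 - exp(-rate * tp)),
                      start = list(plateau = p0, rate = r0),
                      lower = c(0, 1e-6), upper = c(1.5, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## flat or otherwise unidentifiable trace: plateau from the data, no rate
    out <- list(plateau = max(mean(y), 0), rate = NA_real_,
                tHalf = NA_real_, baseline = 0,
                rss = sum((y - mean(y))^2), valid = FALSE)
  } else {
    cf <- stats::coef(fit)
    out <- list(plateau = unname(cf["plateau"]), rate = unname(cf["rate"]),
                tHalf = log(2) / unname(cf["rate"]), baseline = 0,
                rss = sum(stats::residuals(fit)^2),
                valid = unname(cf["rate"]) > 0)
  }
  out$mobilityClass <- classifyMobility(out$plateau,
                                        plateauCutoff = plateauCutoff)
  class(out) <- "FrapFit"
  out
}

#' @export
print.FrapFit <- function(x, ...) {
  cat("One-phase-decay FRAP fit:\n")
  cat("  plateau", signif(x$plateau, 4),
      " rate", signif(x$rate, 4), "/s",
      " t1/2", signif(x$tHalf, 4), "s\n")
  cat("  rss", signif(x$rss, 4),
      if (!x$valid) " (rate unidentifiable)" else "",
      " class:", as.character(x$mobilityClass), "\n")
  invisible(x)
}

#' Classify condensate mobility from a recovery plateau
#'
#' Condensates whose recovery plateau reaches the cutoff are called
#' `liquid`; those with minimal molecular exchange (plateau below the cutoff)
#' are called `slow_diffusive`. The cutoff is a package design parameter
#' (default 0.4); a plateau exactly at the cutoff is liquid.
#'
#' @param fit a `"FrapFit"` object or a numeric plateau value.
#' @param plateauCutoff mobility cutoff (default 0.4).
#' @return factor with levels `liquid`, `slow_diffusive`.
#' @examples
#' classifyMobility(0.8)
#' classifyMobility(0.05)
#' @export
classifyMobility <- function(fit, plateauCutoff = 0.4) {
  plateau <- if (inherits(fit, "FrapFit")) fit$plateau else as.numeric(fit)
  factor(ifelse(plateau >= plateauCutoff, "liquid", "slow_diffusive"),
         levels = c("liquid", "slow_diffusive"))
}

#' Summarise a population of FRAP traces
#'
#' Computes the pointwise mean and population SD of the normalised recovery
#' curves over a common time grid, fits each trace, and tallies mobility
#' classes.
#'
#' @param traces a list of [FrapTrace-class] objects (>= 2) sharing one time
#'   grid.
#' @param plateauCutoff mobility cutoff forwarded to the fits.
#' @return A list with `times`, `mean`, `sd` (pointwise over normalised
#'   curves), `fits` (list of `"FrapFit"`), `classFractions` and
#'   `classCounts`.
#' @export
summarizeFrapPopulation <- function(traces, plateauCutoff = 0.4) {
  if (length(traces) < 2L) stop("need at least 2 traces")
  norms <- lapply(traces, normalizeFrapTrace)
  t0 <- norms[[1]]$times
  same <- vapply(norms, function(nf) {
    length(nf$times) == length(t0) && all(nf$times == t0)
  }, logical(1))
  if (!all(same)) stop("traces are not on a common time grid")
  mat <- do.call(rbind, lapply(norms, `[[`, "values"))
  fits <- lapply(norms, fitOnePhaseDecay, plateauCutoff = plateauCutoff)
  cls <- factor(vapply(fits, function(f) as.character(f$mobilityClass),
                       character(1)),
                levels = c("liquid", "slow_diffusive"))
  counts <- table(cls)
  list(times = t0,
       mean = colMeans(mat),
       sd = apply(mat, 2, function(v) sqrt(mean((v - mean(v))^2))),
       fits = fits,
       classFractions = counts / sum(counts),
       classCounts = counts)
}
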