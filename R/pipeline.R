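## End-to-end experiments: generate -> analyse -> report, with presets
## mirroring the study conditions and seeded reproducibility. Every report
## embeds the resolved configuration, the seed and the package version.

#' Study-condition presets
#'
#' Named parameter sets mirroring the measured study conditions:
#'
#' * `assembly$coAlone`: class weights (diffuse, spherical, aggregate) =
#'   (0.16, 0.36, 0.48), the distribution observed for the condensing factor
#'   expressed alone (n = 75 nuclei).
#' * `assembly$triple`: (0.40, 0.60, 0) for co-expression with both NF-Y
#'   subunits, where assembly shifts to predominantly spherical condensates.
#' * `frap$coAlone` / `frap$triple`: slow-diffusive fractions 0.76 and 0.05
#'   among spherical condensates (n = 50), with liquid
#'   (plateau 0.8, rate 0.1/s) and slow (plateau 0.1, rate 0.05/s) recovery
#'   classes on the in vivo 1 s acquisition grid.
#' * `spr$coOnCo` / `spr$nfyb2`: bivalent-model rate constants whose
#'   first-order Kd values are 50 nM (slow dissociation) and 20 nM (faster
#'   dissociation), with a 256 nM two-fold six-point dilution series.
#'
#' @return A nested list of presets.
#' @export
condensatePresets <- function() {
  list(
    assembly = list(
      coAlone = c(diffuse = 0.16, spherical = 0.36, aggregate = 0.48),
      triple  = c(diffuse = 0.40, spherical = 0.60, aggregate = 0.00)
    ),
    frap = list(
      coAlone = list(slowFraction = 0.76),
      triple  = list(slowFraction = 0.05),
      liquid  = list(plateau = 0.8, rate = 0.1),
      slow    = list(plateau = 0.1, rate = 0.05),
      inVivo  = list(frameInterval = 1, duration = 60),
      inVitro = list(frameInterval = 30, duration = 600)
    ),
    spr = list(
      coOnCo = BivalentParams(ka1 = 1e5, kd1 = 5e-3, ka2 = 1e-3,
                              kd2 = 1e-3, Rmax = 100),
      nfyb2  = BivalentParams(ka1 = 1e6, kd1 = 2e-2, ka2 = 5e-4,
                              kd2 = 1e-2, Rmax = 100),
      topConcentration = 256e-9, dilutionFactor = 2, nDilutions = 6L
    )
  )
}

.reportHeader <- function(config, seed) {
  list(config = config, seed = as.integer(seed),
       packageVersion = as.character(utils::packageVersion("condensateR")))
}

#' Run an assembly-classification experiment
#'
#' Generates a synthetic nucleus population, computes per-nucleus signal
#' variance over thresholded foreground, classifies each nucleus with the
#' 0.21/0.45 cutoffs, and reports class fractions together with a Gaussian
#' mixture fit of the variance distribution.
#'
#' @param weights length-3 class weights (diffuse, spherical, aggregate).
#' @param n number of nuclei (default 75).
#' @param seed integer seed.
#' @param thresholds classification cutoffs.
#' @param mixtureK mixture components (default 3; skipped when `n < 5 *
#'   mixtureK` or fitting fails, with a note in the report).
#' @param outputDir optional directory for [writeReport()].
#' @param ... passed to [makeNucleusImage()].
#' @return A report list: `config`, `seed`, `packageVersion`, `perNucleus`
#'   (data frame), `fractions`, `counts`, `mixture`, `accuracy` (agreement
#'   with ground-truth labels).
#' @export
runAssemblyExperiment <- function(weights, n = 75L, seed = 1L,
                                  thresholds = c(0.21, 0.45), mixtureK = 3L,
                                  outputDir = NULL, ...) {
  if (length(n) != 1L || n < 1L) stop("n must be a positive integer")
  pop <- makeNucleusPopulation(weights, n = n, seed = seed, ...)
  variance <- vapply(pop$images, function(im) {
    as.numeric(nucleusSignalVariance(im))
  }, numeric(1))
  cls <- classifyAssembly(variance, thresholds = thresholds)
  fr <- populationFractions(cls)
  mixture <- NULL
  if (n >= 5L * mixtureK) {
    mixture <- tryCatch(fitVarianceMixture(variance, k = mixtureK,
                                           seed = seed),
                        error = function(e) {
                          list(error = conditionMessage(e))
                        })
  }
  report <- c(
    .reportHeader(list(weights = unname(weights), n = n,
                       thresholds = thresholds, mixtureK = mixtureK), seed),
    list(perNucleus = data.frame(id = seq_len(n),
                                 trueClass = as.character(pop$labels),
                                 variance = variance,
                                 class = as.character(cls)),
         fractions = fr$fractions, counts = fr$counts,
         mixture = if (is.list(mixture)) unclass(mixture) else NULL,
         accuracy = mean(as.character(cls) == as.character(pop$labels))))
  if (!is.null(outputDir)) writeReport(report, outputDir)
  report
}

#' Run a FRAP mobility experiment
#'
#' Generates a two-class mixture of synthetic FRAP traces (slow-diffusive
#' and liquid recovery classes), normalises and fits each trace with the
#' one-phase-decay model, classifies by recovery plateau and reports class
#' fractions plus the population mean +/- SD recovery curve.
#'
#' @param slowFraction fraction of slow-diffusive traces in the mixture.
#' @param n number of traces (default 50).
#' @param seed integer seed.
#' @param liquid,slow per-class recovery parameters, lists with `plateau`
#'   and `rate`.
#' @param noiseSd trace noise SD (fraction units).
#' @param acquisitionBleachRate acquisition photobleaching rate, 1/s.
#' @param frameInterval,duration acquisition grid, s.
#' @param plateauCutoff liquid/slow cutoff (default 0.4).
#' @param outputDir optional directory for [writeReport()].
#' @return A report list with `perTrace` (data frame), `fractions`,
#'   `meanCurve` (data frame time/mean/sd; NULL with `degenerate = TRUE`
#'   when n = 1), and ground-truth agreement.
#' @export
runFrapExperiment <- function(slowFraction, n = 50L, seed = 1L,
                              liquid = list(plateau = 0.8, rate = 0.1),
                              slow = list(plateau = 0.1, rate = 0.05),
                              noiseSd = 0.02, acquisitionBleachRate = 0.01,
                              frameInterval = 1, duration = 60,
                              plateauCutoff = 0.4, outputDir = NULL) {
  if (length(n) != 1L || n < 1L) stop("n must be a positive integer")
  if (slowFraction < 0 || slowFraction > 1) {
    stop("slowFraction must be in [0, 1]")
  }
  labels <- .withSeed(seed, {
    ifelse(runif(n) < slowFraction, "slow_diffusive", "liquid")
  })
  gens <- lapply(seq_len(n), function(i) {
    p <- if (labels[i] == "liquid") liquid else slow
    makeFrapTrace(plateau = p$plateau, rate = p$rate,
                  acquisitionBleachRate = acquisitionBleachRate,
                  noiseSd = noiseSd, frameInterval = frameInterval,
                  duration = duration, seed = .childSeed(seed, i))
  })
  traces <- lapply(gens, `[[`, "trace")
  fits <- lapply(traces, function(tr) {
    fitOnePhaseDecay(normalizeFrapTrace(tr), plateauCutoff = plateauCutoff)
  })
  cls <- factor(vapply(fits, function(f) as.character(f$mobilityClass),
                       character(1)),
                levels = c("liquid", "slow_diffusive"))
  counts <- table(cls)
  degenerate <- n < 2L
  meanCurve <- NULL
  if (!degenerate) {
    pop <- summarizeFrapPopulation(traces, plateauCutoff = plateauCutoff)
    meanCurve <- data.frame(time = pop$times, mean = pop$mean, sd = pop$sd)
  }
  report <- c(
    .reportHeader(list(slowFraction = slowFraction, n = n,
                       liquid = liquid, slow = slow, noiseSd = noiseSd,
                       plateauCutoff = plateauCutoff), seed),
    list(perTrace = data.frame(
           id = seq_len(n), trueClass = labels,
           plateau = vapply(fits, `[[`, numeric(1), "plateau"),
           rate = vapply(fits, `[[`, numeric(1), "rate"),
           class = as.character(cls)),
         fractions = counts / sum(counts), counts = counts,
         meanCurve = meanCurve, degenerate = degenerate,
         accuracy = mean(as.character(cls) == labels)))
  if (!is.null(outputDir)) writeReport(report, outputDir)
  report
}

#' Run an SPR kinetics experiment
#'
#' Simulates a seeded noisy dilution series from the bivalent model and
#' refits it globally, reporting the recovered rate constants and the
#' first-order Kd.
#'
#' @param params true [BivalentParams-class] (e.g. from
#'   [condensatePresets()]).
#' @param topConcentration,dilutionFactor,nDilutions dilution series, see
#'   [makeSensorgramSet()].
#' @param relNoiseSd multiplicative noise SD (default 0.01).
#' @param seed integer seed.
#' @param nStarts,perturbFactor multi-start settings: starts are log-normal
#'   perturbations of the true parameters (see [fitBivalent()]).
#' @param outputDir optional directory for [writeReport()].
#' @return A report list with `fit` (parameters), `kdNm` (recovered
#'   first-order Kd, nM), `trueKdNm` and `ssr`.
#' @export
runSprExperiment <- function(params, topConcentration = 256e-9,
                             dilutionFactor = 2, nDilutions = 6L,
                             relNoiseSd = 0.01, seed = 1L, nStarts = 4L,
                             perturbFactor = log(2), outputDir = NULL) {
  stopifnot(is(params, "BivalentParams"))
  gen <- makeSensorgramSet(params, topConcentration = topConcentration,
                           dilutionFactor = dilutionFactor,
                           nDilutions = nDilutions,
                           relNoiseSd = relNoiseSd, seed = seed)
  fit <- fitBivalent(gen$sensorgrams, init = params,
                     perturbFactor = perturbFactor, nStarts = nStarts,
                     seed = .childSeed(seed, 7L),
                     weighting = "relative")  # generator noise is multiplicative
  report <- c(
    .reportHeader(list(topConcentration = topConcentration,
                       dilutionFactor = dilutionFactor,
                       nDilutions = nDilutions, relNoiseSd = relNoiseSd,
                       trueParams = list(ka1 = params@ka1, kd1 = params@kd1,
                                         ka2 = params@ka2, kd2 = params@kd2,
                                         Rmax = params@Rmax)), seed),
    list(fit = list(ka1 = fit$params@ka1, kd1 = fit$params@kd1,
                    ka2 = fit$params@ka2, kd2 = fit$params@kd2,
                    Rmax = fit$params@Rmax),
         kdNm = fit$firstOrderKd * 1e9,
         trueKdNm = firstOrderKd(params) * 1e9,
         ssr = fit$ssr, converged = fit$converged))
  if (!is.null(outputDir)) writeReport(report, outputDir)
  report
}

#' Run an oligomer-state binding experiment
#'
#' Scans the binding simulation over oligomer states, reporting mean bound
#' count per chain versus state and the Spearman monotonicity statistic,
#' plus (optionally) a binding-off control compared with the analytic
#' random-contact expectation.
#'
#' @param states oligomer states (>= 2 required; missing/empty is a
#'   validation error).
#' @param seeds seeds per state.
#' @param wellDepth binding well depth, kT.
#' @param deskScale use the desk-scale composition (32 units, 8 chains,
#'   76 nm box; default TRUE) rather than the full 60/15/120 composition.
#' @param includeControl run the binding-off control (default TRUE).
#' @param nSteps,dt,stride integration settings.
#' @param seed base seed combined with the per-state seeds.
#' @param outputDir optional directory for [writeReport()].
#' @return A report list with `table` (state, mean, sd, se), `spearman`,
#'   and `control` (mean, expected, se, withinTwoSE) when requested.
#' @export
runBindingExperiment <- function(states = 1:5, seeds = 1:3, wellDepth = 9,
                                 deskScale = TRUE, includeControl = TRUE,
                                 nSteps = 2000000L, dt = 0.008,
                                 stride = 1000L, seed = 1L,
                                 outputDir = NULL) {
  if (is.null(states) || length(states) < 2L) {
    stop("'states' must list at least 2 oligomer states")
  }
  comp <- if (deskScale) list(units = 32L, nDna = 8L, boxNm = 76)
          else list(units = 60L, nDna = 15L, boxNm = 120)
  scan <- scanOligomerStates(states = states,
                             seeds = .childSeed(seed, seq_along(seeds)),
                             units = comp$units, nDna = comp$nDna,
                             boxNm = comp$boxNm, wellDepth = wellDepth,
                             nSteps = nSteps, dt = dt, stride = stride)
  control <- NULL
  if (includeControl) {
    csys <- buildSystem(1L, units = comp$units, nDna = comp$nDna,
                        boxNm = comp$boxNm, wellDepth = 0,
                        seed = .childSeed(seed, 999L))
    ## contacts are rare without binding: sample frames more densely (they
    ## decorrelate in a few time units) so the 2-SE comparison has power
    ctraj <- runDynamics(csys, nSteps = nSteps, dt = dt,
                         stride = max(50L, as.integer(stride) %/% 4L),
                         seed = .childSeed(seed, 998L))
    cbd <- boundDistribution(ctraj)
    expd <- randomContactExpectation(csys)
    control <- list(mean = cbd$mean, expected = expd, se = cbd$se,
                    withinTwoSE = is.finite(cbd$se) &&
                      abs(cbd$mean - expd) <= 2 * cbd$se)
  }
  report <- c(
    .reportHeader(list(states = states, nSeeds = length(seeds),
                       wellDepth = wellDepth, deskScale = deskScale,
                       composition = comp, nSteps = nSteps), seed),
    list(table = scan$table, perRun = scan$perRun,
         spearman = scan$spearman, control = control))
  if (!is.null(outputDir)) writeReport(report, outputDir)
  report
}
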