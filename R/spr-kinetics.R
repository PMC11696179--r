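## Bivalent analyte SPR model: forward ODE simulation and global fitting of
## dilution series, with the first-order dissociation constant kd1/ka1 as the
## headline affinity.

## right-hand side of the bivalent analyte ODEs; state = (AB, AB2).
## free ligand sites = Rmax - AB - w * AB2; analyte concentration C is
## constant during association and 0 during dissociation.
.bivalentRhs <- function(t, state, parms) {
  AB <- state[1]; AB2 <- state[2]
  free <- parms$Rmax - AB - parms$w * AB2
  dAB <- parms$ka1 * parms$C * free - parms$kd1 * AB -
    parms$ka2 * AB * free + parms$kd2 * AB2
  dAB2 <- parms$ka2 * AB * free - parms$kd2 * AB2
  list(c(dAB, dAB2))
}

#' Simulate a bivalent-analyte sensorgram
#'
#' Integrates the bivalent analyte model
#' \deqn{d[AB]/dt = k_{a1} C (R_{max} - [AB] - w[AB_2]) - k_{d1}[AB]
#'       - k_{a2}[AB](R_{max} - [AB] - w[AB_2]) + k_{d2}[AB_2]}
#' \deqn{d[AB_2]/dt = k_{a2}[AB](R_{max} - [AB] - w[AB_2]) - k_{d2}[AB_2]}
#' with analyte concentration `conc` during the association phase and 0
#' afterwards; the response is `[AB] + [AB2]`. The doubly bound species
#' contributes to the response with weight `w` (default 1: each captured
#' analyte counts once regardless of valence). Integration uses a stiff-safe
#' solver.
#'
#' @param params a [BivalentParams-class].
#' @param conc analyte concentration, molar (>= 0).
#' @param grid time grid, s (must start at 0).
#' @param phaseBoundary end of the association phase, s (default 60).
#' @param w response weight of the doubly bound species (default 1).
#' @return A [Sensorgram-class].
#' @examples
#' p <- BivalentParams(1e5, 5e-3, 0, 0, 100)
#' sg <- simulateBivalent(p, 50e-9, seq(0, 360))
#' max(response(sg))
#' @export
simulateBivalent <- function(params, conc, grid, phaseBoundary = 60, w = 1) {
  stopifnot(is(params, "BivalentParams"))
  if (conc < 0) stop("conc must be >= 0")
  grid <- as.numeric(grid)
  if (grid[1] != 0) stop("time grid must start at 0")
  if (conc == 0) {
    return(Sensorgram(grid, rep(0, length(grid)), conc,
                      phaseBoundary = phaseBoundary))
  }
  pl <- list(ka1 = params@ka1, kd1 = params@kd1, ka2 = params@ka2,
             kd2 = params@kd2, Rmax = params@Rmax, w = w)
  assoc <- grid[grid <= phaseBoundary]
  dissoc <- grid[grid > phaseBoundary]
  tA <- unique(c(assoc, phaseBoundary))
  pl$C <- conc
  solA <- deSolve::lsoda(c(AB = 0, AB2 = 0), tA, .bivalentRhs, pl,
                         rtol = 1e-8, atol = 1e-10)
  if (attr(solA, "istate")[1] < 0) stop("ODE integration failed (association)")
  respA <- solA[, "AB"] + solA[, "AB2"]
  keepA <- tA %in% assoc
  resp <- respA[keepA]
  if (length(dissoc) > 0) {
    init <- c(AB = unname(solA[nrow(solA), "AB"]),
              AB2 = unname(solA[nrow(solA), "AB2"]))
    pl$C <- 0
    tD <- c(phaseBoundary, dissoc)
    solD <- deSolve::lsoda(init, tD, .bivalentRhs, pl,
                           rtol = 1e-8, atol = 1e-10)
    if (attr(solD, "istate")[1] < 0) {
      stop("ODE integration failed (dissociation)")
    }
    resp <- c(resp, (solD[, "AB"] + solD[, "AB2"])[-1])
  }
  Sensorgram(grid, resp, conc, phaseBoundary = phaseBoundary)
}

#' First-order dissociation constant
#'
#' The first-order Kd of the bivalent model is `kd1 / ka1` (molar).
#'
#' @param params a [BivalentParams-class] or a `"BivalentFit"`.
#' @return Kd in molar.
#' @examples
#' firstOrderKd(BivalentParams(1e5, 5e-3, 1e-3, 1e-3, 100)) * 1e9  # 50 nM
#' @export
firstOrderKd <- function(params) {
  if (inherits(params, "BivalentFit")) params <- params$params
  stopifnot(is(params, "BivalentParams"))
  if (params@ka1 == 0) stop("ka1 is zero: first-order Kd undefined")
  params@kd1 / params@ka1
}

## stacked residuals of a parameter vector (log scale) against all curves;
## optional per-point weights (for multiplicative noise use 1/response)
.bivalentResiduals <- function(logp, sensorgrams, w, weights = NULL) {
  p <- exp(logp)
  params <- try(BivalentParams(p[1], p[2], p[3], p[4], p[5]), silent = TRUE)
  if (inherits(params, "try-error")) return(rep(1e6, 10))
  res <- unlist(lapply(sensorgrams, function(sg) {
    sim <- try(suppressWarnings(
      simulateBivalent(params, sg@analyteConcentration, timePoints(sg),
                       phaseBoundary = sg@phaseBoundary, w = w)),
      silent = TRUE)
    if (inherits(sim, "try-error")) {
      rep(1e6, length(timePoints(sg)))
    } else {
      response(sg) - response(sim)
    }
  }))
  if (!is.null(weights)) res <- res * weights
  res
}

#' Globally fit the bivalent analyte model to a dilution series
#'
#' Fits `ka1, kd1, ka2, kd2, Rmax` by least squares over all sensorgrams of a
#' dilution series simultaneously (all curves share one parameter set), with
#' seeded multi-start in log-parameter space. Starts are drawn log-uniformly
#' over four decades per rate, or, when `init` is supplied, by log-normal
#' perturbation of `init`. With `weighting = "relative"` residuals are
#' scaled by the inverse response (floored at 2% of the maximum response),
#' the appropriate least-squares weighting when the dominant error is
#' multiplicative.
#'
#' @param sensorgrams list of [Sensorgram-class] objects (>= 3 concentrations
#'   recommended; a single concentration triggers an ill-conditioning
#'   warning).
#' @param init optional [BivalentParams-class] around which starts are
#'   perturbed.
#' @param perturbFactor log-SD of the perturbation (in log units, default
#'   `log(3)`).
#' @param nStarts number of seeded starts (default 8).
#' @param seed RNG seed for the starts.
#' @param w response weight of the doubly bound species (default 1).
#' @param weighting `"uniform"` (default) or `"relative"` residual weights.
#' @return A list of class `"BivalentFit"`: `params`
#'   ([BivalentParams-class]), `firstOrderKd` (molar), `ssr`, `nStartsUsed`,
#'   `converged`, `illConditioned`.
#' @export
fitBivalent <- function(sensorgrams, init = NULL, perturbFactor = log(3),
                        nStarts = 8L, seed = 1L, w = 1,
                        weighting = c("uniform", "relative")) {
  weighting <- match.arg(weighting)
  if (!is.list(sensorgrams) || length(sensorgrams) < 1L) {
    stop("'sensorgrams' must be a non-empty list")
  }
  nConc <- length(unique(vapply(sensorgrams,
                                function(sg) sg@analyteConcentration,
                                numeric(1))))
  illCond <- FALSE
  if (nConc < 3L) {
    warning("fewer than 3 analyte concentrations: the bivalent model is ",
            "likely ill-conditioned")
    illCond <- TRUE
  }
  rMax <- max(vapply(sensorgrams, function(sg) max(response(sg)), numeric(1)))
  wts <- if (weighting == "relative") {
    yAll <- unlist(lapply(sensorgrams, response))
    1 / pmax(abs(yAll), 0.02 * rMax)
  } else NULL
  starts <- .withSeed(seed, {
    lapply(seq_len(nStarts), function(i) {
      if (!is.null(init)) {
        base <- log(c(init@ka1, init@kd1, max(init@ka2, 1e-8),
                      max(init@kd2, 1e-8), init@Rmax))
        if (i == 1L) base else base + rnorm(5, 0, perturbFactor)
      } else {
        c(runif(1, log(1e3), log(1e7)),     # ka1
          runif(1, log(1e-4), log(1)),      # kd1
          runif(1, log(1e-6), log(1e-2)),   # ka2
          runif(1, log(1e-4), log(1)),      # kd2
          log(rMax) + runif(1, log(0.5), log(2)))
      }
    })
  })
  best <- NULL
  for (st in starts) {
    ## capture.output: the ODE solver prints diagnostics to the console when
    ## an exploratory start wanders into a pathological parameter corner
    log <- utils::capture.output(
      fit <- try(minpack.lm::nls.lm(
        par = st, fn = .bivalentResiduals, sensorgrams = sensorgrams, w = w,
        weights = wts,
        control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10)),
        silent = TRUE),
      type = "output")
    if (inherits(fit, "try-error")) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
    }
  }
  if (is.null(best)) stop("bivalent fit did not converge from any start")
  p <- exp(best$par)
  params <- BivalentParams(p[1], p[2], p[3], p[4], p[5])
  structure(list(params = params, firstOrderKd = firstOrderKd(params),
                 ssr = best$ssr, nStartsUsed = length(starts),
                 converged = best$info %in% 1:4,
                 illConditioned = illCond),
            class = "BivalentFit")
}

#' @export
print.BivalentFit <- function(x, ...) {
  cat("Global bivalent-analyte fit (", x$nStartsUsed, " starts):\n", sep = "")
  show(x$params)
  cat("  SSR", signif(x$ssr, 5),
      if (!x$converged) " (not converged)" else "",
      if (x$illConditioned) " [ill-conditioned]" else "", "\n")
  invisible(x)
}
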