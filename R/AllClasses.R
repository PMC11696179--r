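#' @import methods
#' @importFrom stats sd rnorm runif rmultinom setNames quantile median mad
#'   dnorm uniroot cor
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib condensateR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## NucleusImage: a 2-D intensity grid with physical pixel size, an optional
## nucleus footprint mask, and a channel tag.
## ---------------------------------------------------------------------------

#' NucleusImage class
#'
#' Container for a single-nucleus fluorescence image: a 2-D grid of
#' non-negative intensities (arbitrary units), the physical pixel size in
#' micrometres, an optional logical mask giving the nucleus footprint, and a
#' channel label.
#'
#' @slot intensities numeric matrix of non-negative, finite intensities.
#' @slot pixelSize single positive numeric, micrometres per pixel.
#' @slot channel single character channel tag (e.g. `"GFP"`).
#' @slot mask logical matrix with the same dimensions as `intensities`, or a
#'   0 x 0 matrix when no mask is attached.
#'
#' @seealso [NucleusImage()], [nucleusSignalVariance()], [maxProject()]
#' @export
setClass("NucleusImage",
  representation(
    intensities = "matrix",
    pixelSize   = "numeric",
    channel     = "character",
    mask        = "matrix"
  ),
  prototype(
    pixelSize = 0.1,
    channel   = "GFP",
    mask      = matrix(logical(0), 0L, 0L)
  )
)

setValidity("NucleusImage", function(object) {
  im <- object@intensities
  if (!is.numeric(im)) return("intensities must be numeric")
  if (any(!is.finite(im))) return("intensities must be finite")
  if (any(im < 0)) return("intensities must be non-negative")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    return("pixelSize must be a single positive number")
  }
  if (length(object@channel) != 1L) return("channel must be a single string")
  m <- object@mask
  if (length(m) > 0L) {
    if (!is.logical(m)) return("mask must be logical")
    if (!identical(dim(m), dim(im))) {
      return("mask must have the same dimensions as intensities")
    }
  }
  TRUE
})

#' Construct a NucleusImage
#'
#' @param intensities numeric matrix of non-negative intensities.
#' @param pixelSize micrometres per pixel.
#' @param channel channel label.
#' @param mask optional logical matrix (nucleus footprint), same shape as
#'   `intensities`.
#' @return A [NucleusImage-class] object.
#' @examples
#' img <- NucleusImage(matrix(runif(64), 8, 8), pixelSize = 0.1)
#' pixelSize(img)
#' @export
NucleusImage <- function(intensities, pixelSize = 0.1, channel = "GFP",
                         mask = NULL) {
  if (is.null(mask)) mask <- matrix(logical(0), 0L, 0L)
  mask <- matrix(as.logical(mask), nrow = nrow(mask), ncol = ncol(mask))
  new("NucleusImage", intensities = intensities, pixelSize = pixelSize,
      channel = channel, mask = mask)
}

#' @describeIn NucleusImage-class intensity matrix accessor
#' @param object,x a `NucleusImage`
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname NucleusImage-class
#' @export
setMethod("intensities", "NucleusImage", function(x) x@intensities)

#' @rdname NucleusImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname NucleusImage-class
#' @export
setMethod("pixelSize", "NucleusImage", function(x) x@pixelSize)

#' @rdname NucleusImage-class
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))

#' @rdname NucleusImage-class
#' @export
setMethod("nucleusMask", "NucleusImage", function(x) {
  if (length(x@mask) == 0L) NULL else x@mask
})

setMethod("show", "NucleusImage", function(object) {
  d <- dim(object@intensities)
  cat("NucleusImage:", d[1], "x", d[2], "px,",
      format(object@pixelSize), "um/px, channel", object@channel, "\n")
  cat("  intensity range [", format(min(object@intensities), digits = 4), ", ",
      format(max(object@intensities), digits = 4), "]",
      if (!is.null(nucleusMask(object))) ", mask attached" else "", "\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## LineProfile: ordered intensities sampled along a wide line ROI.
## ---------------------------------------------------------------------------

#' LineProfile class
#'
#' Ordered intensity values sampled along a line ROI of finite width (the
#' profile used by the spatial clustering index). At least 20 values are
#' required so that 5% tails contain at least one value.
#'
#' @slot values ordered numeric intensities along the line.
#' @slot lineWidth line width in micrometres (default 3).
#' @slot source identifier of the source nucleus.
#' @seealso [extractLineProfile()], [spatialClusteringIndex()]
#' @export
setClass("LineProfile",
  representation(values = "numeric", lineWidth = "numeric",
                 source = "character"),
  prototype(lineWidth = 3, source = NA_character_)
)

setValidity("LineProfile", function(object) {
  if (length(object@values) < 20L) {
    return("a LineProfile needs >= 20 values so that 5% tails are non-empty")
  }
  if (any(!is.finite(object@values))) return("values must be finite")
  if (object@lineWidth <= 0) return("lineWidth must be positive")
  TRUE
})

#' @rdname LineProfile-class
#' @param values,lineWidth,source see slots.
#' @export
LineProfile <- function(values, lineWidth = 3, source = NA_character_) {
  new("LineProfile", values = as.numeric(values), lineWidth = lineWidth,
      source = as.character(source))
}

setMethod("show", "LineProfile", function(object) {
  cat("LineProfile:", length(object@values), "samples, width",
      object@lineWidth, "um, source", object@source, "\n")
})

## ---------------------------------------------------------------------------
## FrapTrace: bleach + reference ROI time series.
## ---------------------------------------------------------------------------

#' FrapTrace class
#'
#' A FRAP time series: uniform time grid, intensities of the bleached ROI and
#' of an equally sized unbleached reference ROI (used to correct acquisition
#' photobleaching), the number of prebleach frames, and the index of the first
#' post-bleach frame.
#'
#' @slot times time points in seconds (uniform grid).
#' @slot bleachRoi intensity series of the bleached ROI.
#' @slot referenceRoi intensity series of the unbleached reference ROI.
#' @slot prebleachFrames number of frames acquired before the bleach pulse.
#' @slot bleachFrameIndex index (1-based) of the first post-bleach frame.
#' @seealso [normalizeFrapTrace()], [fitOnePhaseDecay()]
#' @export
setClass("FrapTrace",
  representation(times = "numeric", bleachRoi = "numeric",
                 referenceRoi = "numeric", prebleachFrames = "integer",
                 bleachFrameIndex = "integer")
)

setValidity("FrapTrace", function(object) {
  n <- length(object@times)
  if (length(object@bleachRoi) != n || length(object@referenceRoi) != n) {
    return("bleachRoi and referenceRoi must have the same length as times")
  }
  if (n >= 2 && any(diff(object@times) <= 0)) {
    return("times must be strictly increasing")
  }
  if (object@prebleachFrames < 1L) return("prebleachFrames must be >= 1")
  if (object@bleachFrameIndex <= object@prebleachFrames) {
    return("bleachFrameIndex must follow the prebleach frames")
  }
  TRUE
})

#' @rdname FrapTrace-class
#' @param times,bleachRoi,referenceRoi,prebleachFrames,bleachFrameIndex see
#'   slots.
#' @export
FrapTrace <- function(times, bleachRoi, referenceRoi,
                      prebleachFrames = 5L,
                      bleachFrameIndex = prebleachFrames + 1L) {
  new("FrapTrace", times = as.numeric(times),
      bleachRoi = as.numeric(bleachRoi),
      referenceRoi = as.numeric(referenceRoi),
      prebleachFrames = as.integer(prebleachFrames),
      bleachFrameIndex = as.integer(bleachFrameIndex))
}

setMethod("show", "FrapTrace", function(object) {
  cat("FrapTrace:", length(object@times), "frames,",
      object@prebleachFrames, "prebleach, dt =",
      format(stats::median(diff(object@times))), "s\n")
})

## ---------------------------------------------------------------------------
## Sensorgram / BivalentParams: SPR data and kinetic constants.
## ---------------------------------------------------------------------------

#' BivalentParams class
#'
#' Rate constants of the bivalent analyte SPR model: a bivalent analyte first
#' binds one immobilised ligand (`ka1`, `kd1`; the first-order step whose
#' dissociation constant is `kd1/ka1`), after which its second module can
#' capture a neighbouring ligand (`ka2` in surface-response units, `kd2`).
#'
#' @slot ka1 association rate of the first step, 1/(M s).
#' @slot kd1 dissociation rate of the first step, 1/s.
#' @slot ka2 association rate of the second step, 1/(RU s).
#' @slot kd2 dissociation rate of the second step, 1/s.
#' @slot Rmax surface binding capacity, RU.
#' @seealso [simulateBivalent()], [fitBivalent()], [firstOrderKd()]
#' @export
setClass("BivalentParams",
  representation(ka1 = "numeric", kd1 = "numeric", ka2 = "numeric",
                 kd2 = "numeric", Rmax = "numeric")
)

setValidity("BivalentParams", function(object) {
  v <- c(object@ka1, object@kd1, object@ka2, object@kd2, object@Rmax)
  if (length(v) != 5L || any(!is.finite(v))) return("all rates must be finite")
  if (any(v < 0)) return("rates must be non-negative")
  if (object@Rmax <= 0) return("Rmax must be positive")
  TRUE
})

#' @rdname BivalentParams-class
#' @param ka1,kd1,ka2,kd2,Rmax see slots.
#' @export
BivalentParams <- function(ka1, kd1, ka2, kd2, Rmax) {
  new("BivalentParams", ka1 = ka1, kd1 = kd1, ka2 = ka2, kd2 = kd2,
      Rmax = Rmax)
}

setMethod("show", "BivalentParams", function(object) {
  cat("BivalentParams: ka1 =", format(object@ka1), "/M/s, kd1 =",
      format(object@kd1), "/s, ka2 =", format(object@ka2), "/RU/s, kd2 =",
      format(object@kd2), "/s, Rmax =", format(object@Rmax), "RU\n")
  cat("  first-order Kd =", format(firstOrderKd(object) * 1e9), "nM\n")
})

#' Sensorgram class
#'
#' A single SPR sensorgram: response (RU) versus time at one analyte
#' concentration, with the boundary between the association and dissociation
#' phases. Defaults mirror a 60 s injection followed by 300 s of dissociation.
#'
#' @slot times time points in seconds.
#' @slot response response in RU.
#' @slot analyteConcentration analyte concentration in molar.
#' @slot phaseBoundary time (s) at which association ends.
#' @seealso [simulateBivalent()], [fitBivalent()]
#' @export
setClass("Sensorgram",
  representation(times = "numeric", response = "numeric",
                 analyteConcentration = "numeric", phaseBoundary = "numeric"),
  prototype(phaseBoundary = 60)
)

setValidity("Sensorgram", function(object) {
  if (length(object@response) != length(object@times)) {
    return("response must have the same length as times")
  }
  if (any(!is.finite(object@response))) return("response must be finite")
  if (length(object@analyteConcentration) != 1L ||
      object@analyteConcentration < 0) {
    return("analyteConcentration must be a single non-negative number")
  }
  TRUE
})

#' @rdname Sensorgram-class
#' @param times,response,analyteConcentration,phaseBoundary see slots.
#' @export
Sensorgram <- function(times, response, analyteConcentration,
                       phaseBoundary = 60) {
  new("Sensorgram", times = as.numeric(times), response = as.numeric(response),
      analyteConcentration = analyteConcentration,
      phaseBoundary = phaseBoundary)
}

setMethod("show", "Sensorgram", function(object) {
  cat("Sensorgram:", length(object@times), "points, C =",
      format(object@analyteConcentration * 1e9), "nM, association ends at",
      object@phaseBoundary, "s\n")
})

#' @rdname Sensorgram-class
#' @export
setGeneric("response", function(x) standardGeneric("response"))

#' @rdname Sensorgram-class
#' @export
setMethod("response", "Sensorgram", function(x) x@response)

#' Time grid accessor
#' @param x a `FrapTrace` or `Sensorgram`
#' @return numeric vector of time points (seconds).
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname timePoints
#' @export
setMethod("timePoints", "FrapTrace", function(x) x@times)

#' @rdname timePoints
#' @export
setMethod("timePoints", "Sensorgram", function(x) x@times)

## ---------------------------------------------------------------------------
## ReducedSystem: coarse-grained oligomer + DNA system in a periodic box.
## ---------------------------------------------------------------------------

#' ReducedSystem class
#'
#' Bead-level representation of oligomeric protein complexes and motif-bearing
#' DNA chains in a cubic periodic box. One bead represents one binding unit
#' (one monomeric complex); DNA is a chain of beads, four of which per chain
#' carry binding motifs. A unit is counted as bound to a chain when its
#' minimum-image distance to any motif bead of that chain is within
#' `contactCutoff` (1.2 nm).
#'
#' @slot boxLength cubic box edge, nm.
#' @slot positions N x 3 matrix of bead coordinates (nm), wrapped into the box.
#' @slot dnaChains list of integer vectors: bead row indices of each chain.
#' @slot motifIndices list of integer vectors: motif bead rows per chain.
#' @slot complexes list of integer vectors: unit bead rows per complex.
#' @slot oligomerState integer, units per complex (1-5; remainder complexes
#'   are monomers).
#' @slot contactCutoff contact distance, nm (default 1.2).
#' @slot bindingWellDepth attractive well depth between units and motif beads,
#'   kT.
#' @slot temperature reduced temperature (kT units; default 1).
#' @slot bondLength DNA bead spacing, nm.
#' @slot unitBondLength rest length of intra-complex links, nm.
#' @slot seed RNG seed used to build the system.
#' @seealso [buildSystem()], [runDynamics()], [countContacts()]
#' @export
setClass("ReducedSystem",
  representation(
    boxLength = "numeric", positions = "matrix", dnaChains = "list",
    motifIndices = "list", complexes = "list", oligomerState = "integer",
    contactCutoff = "numeric", bindingWellDepth = "numeric",
    temperature = "numeric", bondLength = "numeric",
    unitBondLength = "numeric", seed = "integer"
  ),
  prototype(contactCutoff = 1.2, temperature = 1)
)

setValidity("ReducedSystem", function(object) {
  if (object@boxLength <= 0) return("boxLength must be positive")
  if (ncol(object@positions) != 3L) return("positions must be N x 3")
  if (any(object@positions < 0) || any(object@positions >= object@boxLength)) {
    return("all coordinates must be wrapped into [0, boxLength)")
  }
  if (!all(lengths(object@motifIndices) == 4L)) {
    return("each DNA chain must carry exactly 4 motif sites")
  }
  if (object@oligomerState < 1L || object@oligomerState > 5L) {
    return("oligomerState must be in 1..5")
  }
  s <- object@oligomerState
  sizes <- lengths(object@complexes)
  if (!all(sizes %in% c(1L, s))) {
    return("complexes must be s-mers plus monomeric remainder")
  }
  TRUE
})

setMethod("show", "ReducedSystem", function(object) {
  cat("ReducedSystem:", length(object@dnaChains), "DNA chains,",
      length(object@complexes), "complexes (s =", object@oligomerState,
      "),", sum(lengths(object@complexes)), "binding units\n")
  cat("  box", object@boxLength, "nm, contact cutoff", object@contactCutoff,
      "nm, well depth", object@bindingWellDepth, "kT\n")
})

#' Total number of binding units in a ReducedSystem
#' @param x a `ReducedSystem`
#' @return integer count of binding units.
#' @export
setGeneric("nBindingUnits", function(x) standardGeneric("nBindingUnits"))

#' @rdname nBindingUnits
#' @export
setMethod("nBindingUnits", "ReducedSystem",
          function(x) sum(lengths(x@complexes)))
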