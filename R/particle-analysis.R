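## Single-particle analysis on TIRF-like images: Laplacian-of-Gaussian spot
## detection with sub-pixel refinement, background-corrected total-intensity
## quantification, and mutual-nearest-neighbour colocalization.

## scale-normalised LoG kernel (negated so bright blobs give positive peaks)
.logKernel <- function(sigma) {
  h <- ceiling(4 * sigma)
  ax <- -h:h
  xx <- matrix(rep(ax, each = length(ax)), length(ax))
  yy <- t(xx)
  g <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
  g <- g / sum(g)
  lap <- (xx^2 + yy^2 - 2 * sigma^2) / sigma^4 * g
  k <- -sigma^2 * (lap - mean(lap))
  k
}

#' Detect diffraction-limited spots
#'
#' Laplacian-of-Gaussian blob detection: the image is convolved with a
#' scale-normalised LoG kernel matched to `sigmaExpected`, local maxima of
#' the response above `qualityThreshold` are kept, duplicates within
#' `2 * sigmaExpected` are removed by non-maximum suppression (strongest
#' response wins), and positions are refined to sub-pixel accuracy by
#' quadratic interpolation of the response.
#'
#' @param image numeric matrix.
#' @param sigmaExpected expected spot sigma, pixels (default 1.5).
#' @param qualityThreshold minimum LoG response; `NULL` (default) uses a
#'   robust automatic threshold (`5 * mad` of the response above its median).
#' @return A data frame of spots with 0-based sub-pixel `x` (column), `y`
#'   (row), `sigma` and `quality` (LoG response); zero rows when nothing is
#'   found.
#' @examples
#' f <- makeParticleField(3, seed = 1)
#' nrow(detectSpots(f$image))
#' @export
detectSpots <- function(image, sigmaExpected = 1.5, qualityThreshold = NULL) {
  im <- as.matrix(image)
  if (any(!is.finite(im))) stop("image must be finite")
  k <- .logKernel(sigmaExpected)
  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(im), k,
                                              boundary = "replicate"))
  if (is.null(qualityThreshold)) {
    qualityThreshold <- median(resp) + 5 * mad(resp)
  }
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3L || nc < 3L) return(.emptySpots())
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  isMax <- core > qualityThreshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & core >= resp[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(.emptySpots())
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  q <- resp[cbind(rows, cols)]
  ## non-maximum suppression within 2 sigma, strongest first
  ord <- order(q, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]; q <- q[ord]
  keep <- logical(length(q))
  minD2 <- (2 * sigmaExpected)^2
  for (i in seq_along(q)) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- which(keep[seq_len(i - 1L)])
    d2 <- (rows[kept] - rows[i])^2 + (cols[kept] - cols[i])^2
    keep[i] <- all(d2 >= minD2)
  }
  rows <- rows[keep]; cols <- cols[keep]; q <- q[keep]
  ## sub-pixel refinement by 1-D quadratic interpolation per axis
  subOff <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    ifelse(abs(den) < 1e-12, 0, pmin(pmax(0.5 * (m1 - p1) / den, -0.5), 0.5))
  }
  inb <- rows > 1 & rows < nr & cols > 1 & cols < nc
  dy <- dx <- numeric(length(q))
  if (any(inb)) {
    r <- rows[inb]; c <- cols[inb]
    dy[inb] <- subOff(resp[cbind(r - 1L, c)], resp[cbind(r, c)],
                      resp[cbind(r + 1L, c)])
    dx[inb] <- subOff(resp[cbind(r, c - 1L)], resp[cbind(r, c)],
                      resp[cbind(r, c + 1L)])
  }
  data.frame(x = cols - 1 + dx, y = rows - 1 + dy,
             sigma = rep(sigmaExpected, length(q)), quality = q)
}

.emptySpots <- function() {
  data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
             quality = numeric(0))
}

#' Background-corrected total spot intensity
#'
#' Sums pixel values inside a disk around the spot and subtracts the local
#' background, estimated as the median of an annulus around the disk times
#' the disk area. Spots whose disk is clipped by the image border are
#' flagged.
#'
#' @param image numeric matrix.
#' @param x,y 0-based spot centre (column, row).
#' @param radius integration radius, pixels (default `3 * sigma` with
#'   `sigma = 1.5`).
#' @param annulusWidth width of the background annulus, pixels.
#' @return total intensity (numeric) with attribute `"clipped"` (logical).
#' @export
spotTotalIntensity <- function(image, x, y, radius = 4.5, annulusWidth = 3) {
  im <- as.matrix(image)
  nr <- nrow(im); nc <- ncol(im)
  rows <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  cols <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  d2 <- (rows - y)^2 + (cols - x)^2
  disk <- d2 <= radius^2
  ann <- d2 > radius^2 & d2 <= (radius + annulusWidth)^2
  clipped <- (x - radius < 0) || (y - radius < 0) ||
    (x + radius > nc - 1) || (y + radius > nr - 1)
  if (!any(disk)) stop("integration disk contains no pixels")
  bg <- if (any(ann)) median(im[ann]) else 0
  out <- sum(im[disk]) - bg * sum(disk)
  attr(out, "clipped") <- clipped
  out
}

#' Quantify a table of detected spots
#'
#' Applies [spotTotalIntensity()] to each spot; border-clipped spots are
#' excluded by default.
#'
#' @param image numeric matrix.
#' @param spots data frame from [detectSpots()].
#' @param radiusFactor integration radius as a multiple of the spot sigma
#'   (default 3).
#' @param keepClipped keep border-clipped spots (default FALSE).
#' @return `spots` with columns `intensity` and `clipped` added (clipped
#'   spots removed unless `keepClipped`).
#' @export
quantifySpots <- function(image, spots, radiusFactor = 3,
                          keepClipped = FALSE) {
  if (nrow(spots) == 0L) {
    spots$intensity <- numeric(0); spots$clipped <- logical(0)
    return(spots)
  }
  res <- lapply(seq_len(nrow(spots)), function(i) {
    v <- spotTotalIntensity(image, spots$x[i], spots$y[i],
                            radius = radiusFactor * spots$sigma[i])
    list(intensity = as.numeric(v), clipped = attr(v, "clipped"))
  })
  spots$intensity <- vapply(res, `[[`, numeric(1), "intensity")
  spots$clipped <- vapply(res, `[[`, logical(1), "clipped")
  if (!keepClipped) spots <- spots[!spots$clipped, , drop = FALSE]
  spots
}

#' Colocalize spots across two channels
#'
#' Mutual-nearest-neighbour matching: a pair (a, b) is matched when b is the
#' nearest B-spot to a, a is the nearest A-spot to b, and their distance is
#' within `radiusPx`. The colocalized fraction is `matched / |A|`.
#'
#' @param spotsA,spotsB data frames with `x`, `y` columns.
#' @param radiusPx matching radius, pixels.
#' @return A list with `pairs` (data frame `a`, `b`, `distance`) and
#'   `fraction`.
#' @examples
#' a <- data.frame(x = c(1, 10), y = c(1, 10))
#' colocalizeChannels(a, a, radiusPx = 2)$fraction  # 1
#' @export
colocalizeChannels <- function(spotsA, spotsB, radiusPx) {
  if (radiusPx <= 0) stop("radiusPx must be positive")
  nA <- nrow(spotsA); nB <- nrow(spotsB)
  if (nA == 0L || nB == 0L) {
    return(list(pairs = data.frame(a = integer(0), b = integer(0),
                                   distance = numeric(0)),
                fraction = 0))
  }
  d <- outer(spotsA$x, spotsB$x, "-")^2 + outer(spotsA$y, spotsB$y, "-")^2
  nnAB <- apply(d, 1, which.min)
  nnBA <- apply(d, 2, which.min)
  aIdx <- which(nnBA[nnAB] == seq_len(nA))
  bIdx <- nnAB[aIdx]
  dist <- sqrt(d[cbind(aIdx, bIdx)])
  ok <- dist <= radiusPx
  list(pairs = data.frame(a = aIdx[ok], b = bIdx[ok], distance = dist[ok]),
       fraction = sum(ok) / nA)
}
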