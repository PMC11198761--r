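#' Outward unit normals along a boundary path
#'
#' The tangent at point i is the central difference of its cyclic
#' neighbors; the normal is the unit perpendicular oriented outward
#' (toward the non-ROI side), decided by probing ROI membership one and
#' two pixels along each candidate direction (ties broken by the direction
#' away from the ROI centroid). Reversing the path orientation leaves the
#' outward normals unchanged.
#'
#' @param points n x 2 ordered (row, col) boundary path, n >= 3.
#' @param roiSlice logical 2D ROI matrix the path was traced on.
#' @return n x 2 matrix of unit outward normals (row, col components).
#' @export
boundaryNormals <- function(points, roiSlice) {
  n <- nrow(points)
  if (n < 3L) stop("path must have at least 3 points")
  roiSlice <- matrix(as.logical(roiSlice), nrow(roiSlice), ncol(roiSlice))
  idx <- which(roiSlice, arr.ind = TRUE)
  centroid <- colMeans(idx)
  nr <- nrow(roiSlice); nc <- ncol(roiSlice)
  inRoi <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc &&
    roiSlice[r, c]
  normals <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    prv <- points[if (i == 1L) n else i - 1L, ]
    nxt <- points[if (i == n) 1L else i + 1L, ]
    tg <- nxt - prv
    if (all(tg == 0)) tg <- c(1, 0)
    tg <- tg / sqrt(sum(tg^2))
    cand <- c(tg[2], -tg[1])
    hits <- function(dirv) {
      s <- 0L
      for (step in 1:2) {
        q <- round(points[i, ] + step * dirv)
        if (inRoi(q[1], q[2])) s <- s + 1L
      }
      s
    }
    hPlus <- hits(cand); hMinus <- hits(-cand)
    if (hPlus < hMinus) normals[i, ] <- cand
    else if (hMinus < hPlus) normals[i, ] <- -cand
    else {
      outward <- points[i, ] - centroid
      normals[i, ] <- if (sum(outward * cand) >= 0) cand else -cand
    }
  }
  normals
}

#' Boundary NOSS differences along normal lines
#'
#' For each boundary point, samples the standardized NOSS at nearest
#' voxels 1..depth outward along the normal and 1..depth inward, and
#' returns the outward mean minus the inward mean. Samples leaving the RP
#' or masked are dropped; a point is dropped when either side has no
#' sample.
#'
#' @param rp a standardized \linkS4class{RPImage}.
#' @param points n x 2 boundary path in slice coordinates.
#' @param normals n x 2 outward unit normals from
#'   \code{\link{boundaryNormals}}.
#' @param params an \linkS4class{EntropyParams}.
#' @return numeric vector of per-point NOSS differences.
#' @export
deltaNossBdy <- function(rp, points, normals, params = entropyParams()) {
  stopifnot(is(rp, "RPImage"))
  if (!rp@standardized) stop("RP must be standardized first")
  v <- rp@intensities
  nr <- nrow(v); nc <- ncol(v)
  out <- numeric(0)
  for (i in seq_len(nrow(points))) {
    pr <- points[i, 1] - rp@origin[1] + 1L
    pc <- points[i, 2] - rp@origin[2] + 1L
    side <- function(sgn) {
      vals <- numeric(0)
      for (s in seq_len(params@normalDepthVox)) {
        q <- round(c(pr, pc) + sgn * s * normals[i, ])
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        x <- v[q[1], q[2]]
        if (!is.na(x)) vals <- c(vals, x)
      }
      vals
    }
    outv <- side(+1); inv <- side(-1)
    if (length(outv) == 0L || length(inv) == 0L) next
    out <- c(out, mean(outv) - mean(inv))
  }
  out
}

#' Shannon entropy of boundary NOSS differences
#'
#' Histograms the differences on a fixed range and returns
#' \eqn{H = -\sum_k p_k \log_2 p_k} over occupied bins, in bits. Values
#' outside the range are clipped into the edge bins.
#'
#' @param values numeric vector of NOSS differences (length >= 2).
#' @param params an \linkS4class{EntropyParams}.
#' @return entropy in bits, in \code{[0, log2(nBins)]}.
#' @examples
#' entropyDeltaNoss(rep(0.1, 10))                      # 0 bits
#' entropyDeltaNoss(c(rep(-0.5, 5), rep(0.5, 5)))      # 1 bit
#' @export
entropyDeltaNoss <- function(values, params = entropyParams()) {
  if (length(values) < 2L) stop("need at least 2 values")
  lo <- params@binRange[1]; hi <- params@binRange[2]
  x <- pmin(hi, pmax(lo, values))
  breaks <- seq(lo, hi, length.out = params@nBins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = params@nBins)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Boundary-entropy baseline over a tumor volume
#'
#' Mirrors \code{\link{runSIR}}'s slice handling: per analyzable slice,
#' extracts and standardizes the RP, traces the boundary, computes outward
#' normals and boundary NOSS differences, and pools the differences across
#' slices into a single entropy (bits) per tumor.
#'
#' @param noss a \linkS4class{ScalarMap} of kind \code{"NOSS"}.
#' @param mask logical 3D tumor mask.
#' @param params an \linkS4class{EntropyParams}.
#' @param sirParamsObj a \linkS4class{SIRParams} providing the RP padding
#'   and slice area filter.
#' @return list with \code{entropy} (bits), \code{nValues}, and
#'   \code{values} (the pooled differences).
#' @export
runEntropyBaseline <- function(noss, mask, params = entropyParams(),
                               sirParamsObj = sirParams()) {
  stopifnot(is(noss, "ScalarMap"))
  v <- noss@values
  if (!identical(dim(v), dim(mask))) stop("NOSS and mask grids differ")
  mask <- array(as.logical(mask), dim(mask))
  vals <- numeric(0)
  for (k in seq_len(dim(v)[3])) {
    roi <- mask[, , k]
    if (sum(roi) < sirParamsObj@minRoiPixels) next
    paths <- traceBoundary(roi, sirParamsObj@minRoiPixels)
    if (length(paths) == 0L) next
    rp <- standardizeRP(extractRP(v[, , k], roi, sirParamsObj@rpPad))
    for (pp in paths) {
      if (nrow(pp$points) < 3L) next
      normals <- boundaryNormals(pp$points, roi)
      vals <- c(vals, deltaNossBdy(rp, pp$points, normals, params))
    }
  }
  if (length(vals) < 2L) stop("no analyzable boundary")
  list(entropy = entropyDeltaNoss(vals, params), nValues = length(vals),
       values = vals)
}
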