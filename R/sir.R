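#' Rectangular-partial (RP) NOSS image
#'
#' NOSS sub-image covering the per-slice tumor-ROI bounding box extended by
#' a fixed padding in the horizontal and vertical directions, intensity
#' standardized so its maximum valid value is 1.
#'
#' @slot intensities 2D matrix, \code{NA} where the NOSS map is masked.
#' @slot origin (row, col) 1-based offset of the RP's top-left pixel in the
#'   parent slice.
#' @slot standardized whether the intensities were divided by their max.
#' @slot degenerateFlag set when standardization was impossible (all-zero
#'   or all-masked RP).
#' @export
setClass("RPImage",
  representation(intensities = "matrix", origin = "integer",
    standardized = "logical", degenerateFlag = "logical"))

# 8-connected component labeling of a logical matrix (stack-based).
.labelComponents8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    stack <- seed
    lab[seed] <- cur
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((j - 1L) %% nr) + 1L
      cc <- ((j - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1L || rr > nr || ccc < 1L || ccc > nc) next
        if (mask[rr, ccc] && lab[rr, ccc] == 0L) {
          lab[rr, ccc] <- cur
          stack <- c(stack, (ccc - 1L) * nr + rr)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# Clockwise Moore-neighbor trace of one connected component, starting at
# the top-left (row-major first) pixel, with Jacob's stopping criterion.
.mooreTrace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inMask <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  start <- NULL
  for (r in seq_len(nr)) {
    cs <- which(mask[r, ])
    if (length(cs)) { start <- c(r, cs[1]); break }
  }
  if (is.null(start)) return(matrix(integer(0), ncol = 2))
  # clockwise Moore neighborhood: N, NE, E, SE, S, SW, W, NW
  dirs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L,
                   0L, -1L, -1L, -1L), ncol = 2, byrow = TRUE)
  p <- start
  b0 <- c(start[1], start[2] - 1L)  # west of start is background
  b <- b0
  path <- matrix(start, ncol = 2)
  maxIter <- 4L * sum(mask) + 8L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter) break
    off <- b - p
    i0 <- which(dirs[, 1] == off[1] & dirs[, 2] == off[2])
    moved <- FALSE
    for (s in 1:8) {
      idx <- ((i0 - 1L + s) %% 8L) + 1L
      cand <- p + dirs[idx, ]
      if (inMask(cand[1], cand[2])) {
        prevIdx <- ((i0 - 1L + s - 1L) %% 8L) + 1L
        b <- p + dirs[prevIdx, ]
        p <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # isolated pixel
    if (p[1] == start[1] && p[2] == start[2] &&
        b[1] == b0[1] && b[2] == b0[2]) break
    path <- rbind(path, p)
  }
  path
}

# TRUE for matrix pixels with >= 1 face-neighbor outside the mask.
.faceBoundary2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nbrOut <- (!pad[1:nr, 2:(nc + 1L)]) + (!pad[3:(nr + 2L), 2:(nc + 1L)]) +
            (!pad[2:(nr + 1L), 1:nc]) + (!pad[2:(nr + 1L), 3:(nc + 2L)])
  core & nbrOut > 0
}

#' Trace tumor-ROI boundaries on one slice
#'
#' One closed path per 8-connected ROI component with area at least
#' \code{minArea}: Moore-neighbor tracing, clockwise, starting at the
#' top-left boundary pixel, restricted to boundary pixels (ROI pixels with
#' at least one face-neighbor outside the ROI), duplicates removed keeping
#' first occurrence.
#'
#' @param roiSlice logical (or 0/1) 2D matrix.
#' @param minArea minimum component area in pixels (default 5).
#' @return list of components; each a list with \code{points} (n x 2
#'   integer matrix of ordered (row, col)) and \code{componentId}.
#' @examples
#' roi <- matrix(FALSE, 9, 9); roi[3:7, 3:7] <- TRUE
#' length(traceBoundary(roi)[[1]]$points[, 1])  # 16 boundary pixels
#' @export
traceBoundary <- function(roiSlice, minArea = 5L) {
  roiSlice <- matrix(as.logical(roiSlice), nrow(roiSlice), ncol(roiSlice))
  out <- list()
  if (!any(roiSlice)) return(out)
  lab <- .labelComponents8(roiSlice)
  bnd <- .faceBoundary2d(roiSlice)
  for (compId in seq_len(lab$n)) {
    comp <- lab$labels == compId
    if (sum(comp) < minArea) next
    path <- .mooreTrace(comp)
    keep <- bnd[cbind(path[, 1], path[, 2])]
    path <- path[keep, , drop = FALSE]
    path <- path[!duplicated(path), , drop = FALSE]
    if (nrow(path) == 0L) next
    out[[length(out) + 1L]] <- list(points = path, componentId = compId)
  }
  out
}

#' Extract the rectangular-partial NOSS image for one slice
#'
#' The RP covers the ROI bounding box extended by \code{pad} pixels in the
#' horizontal and vertical directions, clipped at the slice edges. Masked
#' NOSS pixels stay masked.
#'
#' @param nossSlice numeric 2D matrix (NA where masked).
#' @param roiSlice logical 2D matrix, non-empty.
#' @param pad padding in pixels (default 3).
#' @return an \linkS4class{RPImage} (not yet standardized).
#' @export
extractRP <- function(nossSlice, roiSlice, pad = 3L) {
  roiSlice <- matrix(as.logical(roiSlice), nrow(roiSlice), ncol(roiSlice))
  if (!any(roiSlice)) stop("empty ROI on slice")
  idx <- which(roiSlice, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad)
  r1 <- min(nrow(nossSlice), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad)
  c1 <- min(ncol(nossSlice), max(idx[, 2]) + pad)
  new("RPImage", intensities = nossSlice[r0:r1, c0:c1, drop = FALSE],
      origin = c(as.integer(r0), as.integer(c0)),
      standardized = FALSE, degenerateFlag = FALSE)
}

#' Standardize an RP image to unit maximum
#'
#' Divides all valid intensities by the maximum valid intensity so the RP
#' maximum is 1, giving consistent contrast across patients. An all-zero
#' or all-masked RP is left unchanged and flagged degenerate.
#'
#' @param rp an \linkS4class{RPImage}.
#' @return the standardized \linkS4class{RPImage}.
#' @export
standardizeRP <- function(rp) {
  stopifnot(is(rp, "RPImage"))
  if (rp@standardized) stop("RP already standardized")
  v <- rp@intensities
  mx <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    rp@degenerateFlag <- TRUE
  } else {
    rp@intensities <- v / mx
  }
  rp@standardized <- TRUE
  rp
}

# size x size patch values centered at (row, col), indices clamped to the
# RP (edge replication).
.patchValues <- function(intensities, point, size) {
  half <- (size - 1L) %/% 2L
  rows <- pmin(nrow(intensities), pmax(1L, point[1] + (-half):half))
  cols <- pmin(ncol(intensities), pmax(1L, point[2] + (-half):half))
  intensities[rows, cols, drop = FALSE]
}

#' Select the neighborhood patch for a boundary point
#'
#' Default 3x3 patch centered at the point (center included). When the
#' absolute difference between the 3x3 patch mean and the point intensity
#' is below the escalation threshold (default 0.065), the patch is
#' enlarged to 5x5 to capture more boundary information. Entries falling
#' outside the RP are filled by edge replication; masked entries are
#' excluded from the patch statistics.
#'
#' @param rp a standardized \linkS4class{RPImage}.
#' @param point (row, col) in RP coordinates, 1-based.
#' @param params a \linkS4class{SIRParams}.
#' @return a \linkS4class{Patch}.
#' @export
selectPatch <- function(rp, point, params = sirParams()) {
  stopifnot(is(rp, "RPImage"))
  if (!rp@standardized) stop("RP must be standardized first")
  if (point[1] < 1L || point[1] > nrow(rp@intensities) ||
      point[2] < 1L || point[2] > ncol(rp@intensities))
    stop("point lies outside the RP")
  iA <- rp@intensities[point[1], point[2]]
  v3 <- .patchValues(rp@intensities, point, params@patchDefault)
  m3 <- mean(v3, na.rm = TRUE)
  escalate <- is.finite(m3) && is.finite(iA) &&
    abs(m3 - iA) < params@patchEscalation
  size <- if (escalate) params@patchLarge else params@patchDefault
  v <- if (escalate) .patchValues(rp@intensities, point, size) else v3
  valid <- v[!is.na(v)]
  st <- if (length(valid))
    c(min = min(valid), max = max(valid), mean = mean(valid))
  else c(min = NA_real_, max = NA_real_, mean = NA_real_)
  new("Patch", center = as.numeric(point), size = as.integer(size),
      values = v, stats = st)
}

#' Classify one boundary point with the SIR decision function
#'
#' A point is non-adherent if any of three conditions holds, evaluated in
#' order:
#' \itemize{
#'   \item Condition I: the point intensity falls outside 85\% of the RP
#'     maximum or 115\% of the RP minimum (a distinct hyper- or
#'     hypo-intense boundary);
#'   \item Condition II: the point differs from the patch mean by more
#'     than \eqn{\tau}, 20\% of the patch intensity range (a discernible
#'     but less distinct contrast);
#'   \item Condition III: the point is within \eqn{\tau} of the patch mean
#'     but the patch range exceeds 80\% of the point intensity (large
#'     local variation interfering with visual inspection).
#' }
#'
#' @param iA point intensity on the standardized RP.
#' @param patch the point's \linkS4class{Patch}.
#' @param rpMax,rpMin extrema of the valid standardized RP intensities.
#' @param params a \linkS4class{SIRParams}.
#' @return list with \code{nonAdherent} (logical) and \code{condition}
#'   ("I", "II", "III" or "none" — the first condition that fired).
#' @export
classifyPoint <- function(iA, patch, rpMax, rpMin, params = sirParams()) {
  stopifnot(is(patch, "Patch"))
  pMin <- patch@stats[["min"]]
  pMax <- patch@stats[["max"]]
  pMean <- patch@stats[["mean"]]
  if (iA > params@cond1MaxFrac * rpMax || iA < params@cond1MinFrac * rpMin)
    return(list(nonAdherent = TRUE, condition = "I"))
  tau <- params@cond2TauFrac * (pMax - pMin)
  if (abs(iA - pMean) > tau)
    return(list(nonAdherent = TRUE, condition = "II"))
  if ((pMax - pMin) > params@cond3RangeFrac * iA)
    return(list(nonAdherent = TRUE, condition = "III"))
  list(nonAdherent = FALSE, condition = "none")
}

#' Aggregate per-point labels into adhesion percentages
#'
#' Pools boundary-point counts over all slices (point count as the proxy
#' for interface length): the non-adhesion percentage is 100 times the
#' pooled non-adherent count over the pooled point count, not the mean of
#' per-slice percentages.
#'
#' @param points data.frame with columns \code{slice}, \code{row},
#'   \code{col}, \code{nonAdherent} (logical), \code{condition}.
#' @param labelVol optional integer overlay volume to attach.
#' @param nUnanalyzable count of boundary points with undefined NOSS.
#' @return an \linkS4class{AdhesionResult}.
#' @export
adhesionPercentages <- function(points, labelVol = array(0L, c(0L, 0L, 0L)),
                                nUnanalyzable = 0L) {
  if (is.null(points) || nrow(points) == 0L) stop("no analyzable boundary")
  agg <- stats::aggregate(points$nonAdherent,
                          by = list(slice = points$slice),
                          FUN = function(x) c(n = length(x), na = sum(x)))
  perSlice <- data.frame(slice = agg$slice,
                         nPoints = agg$x[, "n"],
                         nNonAdherent = agg$x[, "na"])
  nonPct <- 100 * sum(points$nonAdherent) / nrow(points)
  cc <- c(I = sum(points$condition == "I"),
          II = sum(points$condition == "II"),
          III = sum(points$condition == "III"))
  new("AdhesionResult", points = points, perSlice = perSlice,
      nonAdhesionPct = nonPct, adhesionPct = 100 - nonPct,
      conditionCounts = as.integer(cc) |> stats::setNames(names(cc)),
      nUnanalyzable = as.integer(nUnanalyzable), labelVolume = labelVol)
}

#' Run slip interface recognition over a tumor volume
#'
#' For each axial slice whose ROI area passes the minimum-pixel filter:
#' extract and standardize the RP NOSS image, trace the ROI boundary, and
#' classify every boundary point with the three-condition decision
#' function; then pool the labels into the tumor's non-adhesion and
#' adhesion percentages. Boundary points whose own NOSS is undefined (low
#' wave amplitude) are excluded from the denominator and tallied.
#'
#' @param noss a \linkS4class{ScalarMap} of kind \code{"NOSS"}.
#' @param mask logical (or 0/1) 3D tumor mask on the same grid.
#' @param params a \linkS4class{SIRParams}.
#' @return an \linkS4class{AdhesionResult} including a label overlay volume
#'   (0 non-boundary, 1 adherent, 2 non-adherent).
#' @examples
#' ph <- simulatePhantom(phantomSpec(slipFraction = 1, seed = 5))
#' maps <- computeNOSS(phantomPhase(ph), mask = brainMask(ph))
#' res <- runSIR(maps$noss, tumorMask(ph))
#' nonAdhesionPct(res)
#' @export
runSIR <- function(noss, mask, params = sirParams()) {
  stopifnot(is(noss, "ScalarMap"))
  v <- noss@values
  if (!identical(dim(v), dim(mask))) stop("NOSS and mask grids differ")
  mask <- array(as.logical(mask), dim(mask))
  labelVol <- array(0L, dim(v))
  rows <- list()
  nUn <- 0L
  nSlices <- 0L
  for (k in seq_len(dim(v)[3])) {
    roi <- mask[, , k]
    if (sum(roi) < params@minRoiPixels) next
    paths <- traceBoundary(roi, params@minRoiPixels)
    if (length(paths) == 0L) next
    rp <- standardizeRP(extractRP(v[, , k], roi, params@rpPad))
    valid <- rp@intensities[!is.na(rp@intensities)]
    if (length(valid) == 0L) next
    rpMax <- max(valid)
    rpMin <- min(valid)
    nSlices <- nSlices + 1L
    for (pp in paths) {
      pts <- pp$points
      for (q in seq_len(nrow(pts))) {
        r <- pts[q, 1]; cc <- pts[q, 2]
        pr <- r - rp@origin[1] + 1L
        pc <- cc - rp@origin[2] + 1L
        iA <- rp@intensities[pr, pc]
        if (is.na(iA)) { nUn <- nUn + 1L; next }
        patch <- selectPatch(rp, c(pr, pc), params)
        cls <- classifyPoint(iA, patch, rpMax, rpMin, params)
        rows[[length(rows) + 1L]] <- data.frame(slice = k, row = r,
          col = cc, nonAdherent = cls$nonAdherent,
          condition = cls$condition)
        labelVol[r, cc, k] <- if (cls$nonAdherent) 2L else 1L
      }
    }
  }
  if (nSlices == 0L) stop("no slice passes the ROI area filter")
  points <- do.call(rbind, rows)
  adhesionPercentages(points, labelVol, nUn)
}
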