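#' Decode encoded phase to displacement
#'
#' Subtracts the opposite-polarity phase images so static phase and
#' common-mode noise cancel: \eqn{u_d(t) = (\phi_{+d}(t) - \phi_{-d}(t)) /
#' (2 s)} for each axis d and offset t.
#'
#' @param phase a \linkS4class{PhaseSeries} (unwrapped).
#' @param sensitivity motion-encoding sensitivity in rad per displacement
#'   unit; the NOSS map is invariant to it.
#' @return a \linkS4class{DisplacementField}.
#' @examples
#' ph <- simulatePhantom(phantomSpec(phaseNoiseSD = 0, seed = 2,
#'   gridShape = c(32L, 32L, 32L), spacing = c(2, 2, 2), tumorRadiusMM = 10))
#' u <- phaseToDisplacement(phantomPhase(ph))
#' max(abs(displacement(u) - displacement(displacementTruth(ph))))
#' @export
phaseToDisplacement <- function(phase, sensitivity = 1) {
  stopifnot(is(phase, "PhaseSeries"))
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  nbad <- sum(!is.finite(phase@data))
  if (nbad > 0)
    stop(sprintf("phase contains %d non-finite values; unwrap/repair first", nbad))
  d <- dim(phase@data)
  u <- array(0, c(d[1:4], 3L))
  for (comp in 1:3) {
    u[, , , , comp] <- (phase@data[, , , , 2L * comp - 1L] -
                        phase@data[, , , , 2L * comp]) / (2 * sensitivity)
  }
  DisplacementField(u, phase@spacing)
}

#' Infinitesimal strain tensor at one phase offset
#'
#' Symmetric gradient \eqn{\varepsilon_{ij} = (\partial u_i/\partial x_j +
#' \partial u_j/\partial x_i)/2} by central differences in the interior and
#' one-sided differences at the grid edges, in physical units (per mm).
#'
#' @param uOffset 4D array \code{[nx, ny, nz, component]} for one offset.
#' @param spacing voxel spacing in mm.
#' @return 4D array \code{[nx, ny, nz, 6]} with components ordered
#'   xx, yy, zz, xy, xz, yz.
#' @export
strainTensor <- function(uOffset, spacing) {
  d <- dim(uOffset)
  stopifnot(length(d) == 4L, d[4] == 3L)
  if (any(d[1:3] < 3L)) stop("grid must have >= 3 voxels per axis")
  J <- vector("list", 9L)  # J[[3*(i-1)+j]] = d u_i / d x_j
  for (i in 1:3) for (j in 1:3)
    J[[3L * (i - 1L) + j]] <- .gradientAxis(uOffset[, , , i], spacing[j], j)
  eps <- array(0, c(d[1:3], 6L))
  dimnames(eps) <- c(rep(list(NULL), 3), list(STRAIN_COMPONENTS))
  eps[, , , 1] <- J[[1]]                    # xx
  eps[, , , 2] <- J[[5]]                    # yy
  eps[, , , 3] <- J[[9]]                    # zz
  eps[, , , 4] <- (J[[2]] + J[[4]]) / 2     # xy
  eps[, , , 5] <- (J[[3]] + J[[7]]) / 2     # xz
  eps[, , , 6] <- (J[[6]] + J[[8]]) / 2     # yz
  eps
}

#' Octahedral shear strain
#'
#' Rotation-invariant scalar summary of the shear part of the strain
#' tensor:
#' \deqn{OSS = \tfrac{2}{3}\sqrt{(\varepsilon_{xx}-\varepsilon_{yy})^2 +
#'   (\varepsilon_{yy}-\varepsilon_{zz})^2 +
#'   (\varepsilon_{zz}-\varepsilon_{xx})^2 +
#'   6(\varepsilon_{xy}^2+\varepsilon_{xz}^2+\varepsilon_{yz}^2)}}
#'
#' @param eps strain array \code{[nx, ny, nz, 6]} from
#'   \code{\link{strainTensor}}.
#' @param spacing voxel spacing in mm.
#' @return a \linkS4class{ScalarMap} of kind \code{"OSS_mean"} (a single
#'   offset's OSS; average offsets with \code{\link{meanOSS}}).
#' @export
octahedralShearStrain <- function(eps, spacing) {
  stopifnot(length(dim(eps)) == 4L, dim(eps)[4] == 6L)
  oss <- (2 / 3) * sqrt(
    (eps[, , , 1] - eps[, , , 2])^2 +
    (eps[, , , 2] - eps[, , , 3])^2 +
    (eps[, , , 3] - eps[, , , 1])^2 +
    6 * (eps[, , , 4]^2 + eps[, , , 5]^2 + eps[, , , 6]^2))
  ScalarMap(oss, "OSS_mean", spacing)
}

#' Average OSS over the eight phase offsets
#'
#' @param ossList list of 8 \linkS4class{ScalarMap}s on the same grid.
#' @return a \linkS4class{ScalarMap} of kind \code{"OSS_mean"}.
#' @export
meanOSS <- function(ossList) {
  if (length(ossList) != 8L) stop("expected 8 per-offset OSS maps")
  dims <- lapply(ossList, function(m) dim(m@values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("OSS maps must share one grid")
  acc <- Reduce(`+`, lapply(ossList, mapValues))
  ScalarMap(acc / 8, "OSS_mean", ossList[[1]]@spacing)
}

#' Combined first-harmonic motion amplitude
#'
#' Per voxel and component, the first-harmonic coefficient of the 8-sample
#' displacement series \eqn{X_1 = \sum_t u(t) e^{-2\pi i t/8}} gives the
#' single-sided amplitude \eqn{A_c = 2|X_1|/8}; the combined amplitude is
#' the root sum of squares over the x/y/z components.
#'
#' @param disp a \linkS4class{DisplacementField}.
#' @return a \linkS4class{ScalarMap} of kind \code{"amplitude"}.
#' @export
firstHarmonicAmplitude <- function(disp) {
  stopifnot(is(disp, "DisplacementField"))
  d <- dim(disp@u)
  t <- 0:7
  cw <- cos(2 * pi * t / 8)
  sw <- sin(2 * pi * t / 8)
  total <- array(0, d[1:3])
  for (comp in 1:3) {
    re <- array(0, d[1:3]); im <- array(0, d[1:3])
    for (tt in 1:8) {
      re <- re + disp@u[, , , tt, comp] * cw[tt]
      im <- im - disp@u[, , , tt, comp] * sw[tt]
    }
    total <- total + (2 / 8)^2 * (re^2 + im^2)
  }
  ScalarMap(sqrt(total), "amplitude", disp@spacing)
}

#' Normalized octahedral shear strain (NOSS) map
#'
#' Divides the offset-averaged OSS by the combined first-harmonic motion
#' amplitude. Voxels with amplitude below \code{epsAmp} are masked
#' (\code{NA}) and excluded from all downstream extrema and patch
#' statistics.
#'
#' @param ossMean \linkS4class{ScalarMap} of kind \code{"OSS_mean"}.
#' @param amplitude \linkS4class{ScalarMap} of kind \code{"amplitude"}.
#' @param epsAmp amplitude guard; default \code{NULL} uses
#'   \code{1e-3 * median(amplitude)} over \code{mask} (or all voxels),
#'   a scale-free guard against division blow-up.
#' @param mask optional logical brain mask used for the default guard and
#'   to restrict the map.
#' @return a \linkS4class{ScalarMap} of kind \code{"NOSS"}.
#' @export
nossMap <- function(ossMean, amplitude, epsAmp = NULL, mask = NULL) {
  stopifnot(is(ossMean, "ScalarMap"), is(amplitude, "ScalarMap"))
  if (!identical(dim(ossMean@values), dim(amplitude@values)))
    stop("OSS and amplitude grids differ")
  amp <- amplitude@values
  ref <- if (is.null(mask)) amp else amp[mask]
  if (is.null(epsAmp)) epsAmp <- 1e-3 * stats::median(ref, na.rm = TRUE)
  if (!is.finite(epsAmp) || epsAmp <= 0) epsAmp <- .Machine$double.eps
  valid <- is.finite(amp) & amp >= epsAmp
  if (!is.null(mask)) valid <- valid & mask
  if (!any(valid)) stop("no valid wave amplitude")
  noss <- array(NA_real_, dim(amp))
  noss[valid] <- ossMean@values[valid] / amp[valid]
  ScalarMap(noss, "NOSS", ossMean@spacing)
}

#' Full phase-to-NOSS pipeline
#'
#' Convenience wrapper: decode phase to displacement, optionally smooth,
#' compute the strain tensor and OSS at each of the 8 offsets, average,
#' compute the combined first-harmonic amplitude, and normalize.
#'
#' @param phase a \linkS4class{PhaseSeries}.
#' @param sensitivity motion-encoding sensitivity (rad per displacement
#'   unit).
#' @param mask optional logical brain mask.
#' @param epsAmp amplitude guard passed to \code{\link{nossMap}}.
#' @param smoothSigmaMM optional Gaussian pre-filter applied to each
#'   displacement component before differentiation, sigma in mm
#'   (default 0 = off).
#' @return list with elements \code{noss}, \code{amplitude}, \code{ossMean}
#'   (\linkS4class{ScalarMap}s) and \code{displacement}.
#' @examples
#' ph <- simulatePhantom(phantomSpec(seed = 11))
#' maps <- computeNOSS(phantomPhase(ph), mask = brainMask(ph))
#' maps$noss
#' @export
computeNOSS <- function(phase, sensitivity = 1, mask = NULL, epsAmp = NULL,
                        smoothSigmaMM = 0) {
  disp <- phaseToDisplacement(phase, sensitivity)
  if (smoothSigmaMM > 0) {
    for (tt in 1:8) for (comp in 1:3)
      disp@u[, , , tt, comp] <- .gaussSmooth3d(disp@u[, , , tt, comp],
                                               smoothSigmaMM, disp@spacing)
  }
  ossList <- lapply(1:8, function(tt)
    octahedralShearStrain(
      strainTensor(disp@u[, , , tt, , drop = TRUE], disp@spacing),
      disp@spacing))
  ossMean <- meanOSS(ossList)
  amp <- firstHarmonicAmplitude(disp)
  noss <- nossMap(ossMean, amp, epsAmp = epsAmp, mask = mask)
  list(noss = noss, amplitude = amp, ossMean = ossMean, displacement = disp)
}
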