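#' Specify a synthetic MRE phantom
#'
#' Builds a \linkS4class{PhantomSpec} describing a spherical tumor inclusion
#' in a single background plane shear wave, sampled at 8 phase offsets over
#' one vibration period and encoded along 6 gradient directions, as in a
#' 60 Hz brain MRE acquisition. The interior of the tumor oscillates with
#' its own amplitude and phase lag; over a spherical-cap sector of the
#' surface (the slip sector) the interior field meets the exterior field
#' discontinuously, while elsewhere (adherent sector) it is blended into
#' the exterior over a finite shell so displacement is continuous.
#'
#' @param gridShape grid size in voxels (default 64 x 64 x 32).
#' @param spacing voxel spacing in mm (default 1.875, 1.875, 3 —
#'   a 24 cm FOV reconstructed to 128 in plane, 3 mm slices, cropped).
#' @param tumorCenterVox tumor center in 0-based voxel coordinates
#'   (default grid center).
#' @param tumorRadiusMM tumor radius in mm (default 15).
#' @param slipFraction target slipping fraction of the tumor surface.
#' @param slipAxis unit vector defining the slip cap (default +z).
#' @param waveAmplitudeUM background wave amplitude in um (default 1).
#' @param waveLengthMM shear wavelength in mm (default 30, a typical brain
#'   shear wavelength at 60 Hz).
#' @param waveDirection unit propagation direction (default +x).
#' @param wavePolarization unit polarization orthogonal to the direction
#'   (default +z).
#' @param tumorAmplitudeUM interior oscillation amplitude (default 1).
#' @param tumorPhaseLag interior phase lag in radians (default pi/2).
#' @param blendWidthVox adherent transition-shell width in voxels
#'   (default 6).
#' @param encodingSensitivity motion-encoding sensitivity in rad/um
#'   (default 1).
#' @param phaseNoiseSD Gaussian phase noise SD in radians (default 0.02).
#' @param seed integer seed for the phase noise.
#' @return a validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(slipFraction = 0.5, seed = 7)
#' spec
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 32L),
                        spacing = c(1.875, 1.875, 3),
                        tumorCenterVox = (gridShape - 1) / 2,
                        tumorRadiusMM = 15,
                        slipFraction = 0.5,
                        slipAxis = c(0, 0, 1),
                        waveAmplitudeUM = 1,
                        waveLengthMM = 30,
                        waveDirection = c(1, 0, 0),
                        wavePolarization = c(0, 0, 1),
                        tumorAmplitudeUM = 1,
                        tumorPhaseLag = pi / 2,
                        blendWidthVox = 6,
                        encodingSensitivity = 1,
                        phaseNoiseSD = 0.02,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
    spacing = as.numeric(spacing),
    tumorCenterVox = as.numeric(tumorCenterVox),
    tumorRadiusMM = tumorRadiusMM, slipFraction = slipFraction,
    slipAxis = as.numeric(slipAxis), waveAmplitudeUM = waveAmplitudeUM,
    waveLengthMM = waveLengthMM, waveDirection = as.numeric(waveDirection),
    wavePolarization = as.numeric(wavePolarization),
    tumorAmplitudeUM = tumorAmplitudeUM, tumorPhaseLag = tumorPhaseLag,
    blendWidthVox = blendWidthVox, encodingSensitivity = encodingSensitivity,
    phaseNoiseSD = phaseNoiseSD, nOffsets = 8L, seed = as.integer(seed))
}

# Spherical tumor mask in physical coordinates.
.tumorMask <- function(spec) {
  co <- .coordArrays(spec@gridShape, spec@spacing)
  c0 <- spec@tumorCenterVox * spec@spacing
  dist2 <- (co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2
  dist2 <= spec@tumorRadiusMM^2
}

# Full grid minus a 2-voxel border.
.brainMask <- function(gridShape) {
  m <- array(TRUE, gridShape)
  d <- gridShape
  m[c(1:2, d[1] - 1:0), , ] <- FALSE
  m[, c(1:2, d[2] - 1:0), ] <- FALSE
  m[, , c(1:2, d[3] - 1:0)] <- FALSE
  m
}

#' Label the slipping sector of a tumor surface
#'
#' Surface voxels are tumor-mask voxels with at least one face-neighbor
#' outside the mask. A surface voxel slips when the angle between its
#' radius vector (voxel center minus tumor center, in mm) and the slip
#' axis is within the spherical-cap half-angle \eqn{\theta^*} solving
#' \eqn{(1 - \cos\theta^*)/2 = f}, so the cap covers the requested
#' fraction \eqn{f} of an ideal sphere's area.
#'
#' @param mask logical (or 0/1) 3D tumor mask.
#' @param slipAxis unit 3-vector.
#' @param slipFraction target surface fraction in [0, 1].
#' @param centerVox tumor center, 0-based voxel coordinates.
#' @param spacing voxel spacing in mm.
#' @return list with \code{labels} (data.frame: i, j, k 1-based voxel
#'   indices, slip logical) and \code{realizedFraction}.
#' @examples
#' sp <- phantomSpec(gridShape = c(24L, 24L, 24L), spacing = c(2, 2, 2),
#'                   tumorRadiusMM = 8, slipFraction = 0.5)
#' m <- slipsir:::.tumorMask(sp)
#' lab <- slipSurfaceLabels(m, c(0, 0, 1), 0.5, sp@tumorCenterVox, sp@spacing)
#' lab$realizedFraction
#' @export
slipSurfaceLabels <- function(mask, slipAxis, slipFraction, centerVox,
                              spacing) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("empty ROI")
  if (slipFraction < 0 || slipFraction > 1)
    stop("slipFraction must lie in [0, 1]")
  surf <- which(.surfaceVoxels(mask), arr.ind = TRUE)
  c0 <- centerVox * spacing
  v <- cbind((surf[, 1] - 1) * spacing[1] - c0[1],
             (surf[, 2] - 1) * spacing[2] - c0[2],
             (surf[, 3] - 1) * spacing[3] - c0[3])
  nv <- sqrt(rowSums(v^2))
  cosang <- as.vector(v %*% slipAxis) / nv
  cosang[nv == 0] <- 1
  # cap half-angle: cos(theta*) = 1 - 2 f
  slip <- if (slipFraction <= 0) rep(FALSE, nrow(surf))
          else cosang >= (1 - 2 * slipFraction) - 1e-12
  labels <- data.frame(i = surf[, 1], j = surf[, 2], k = surf[, 3],
                       slip = slip)
  list(labels = labels,
       realizedFraction = if (nrow(labels)) mean(labels$slip) else 0)
}

#' Synthesize the phantom displacement field
#'
#' Outside the tumor the field is a plane shear wave
#' \eqn{\hat{p} A_b \cos(k \cdot r - \theta_t)} at offsets
#' \eqn{\theta_t = 2\pi t/8}; inside, an oscillation with its own amplitude
#' and phase lag. In the adherent sector the interior field is blended into
#' the exterior field by a linear ramp on the radial distance to the
#' boundary over a shell of \code{blendWidthVox} voxels, so displacement is
#' continuous there; in the slip sector no blending is applied, leaving a
#' displacement discontinuity across the boundary.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{DisplacementField} (micrometres).
#' @export
synthesizeDisplacement <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  co <- .coordArrays(gs, spec@spacing)
  c0 <- spec@tumorCenterVox * spec@spacing
  kvec <- (2 * pi / spec@waveLengthMM) * spec@waveDirection
  karg <- kvec[1] * co$x + kvec[2] * co$y + kvec[3] * co$z
  dx <- co$x - c0[1]; dy <- co$y - c0[2]; dz <- co$z - c0[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  inside <- dist <= spec@tumorRadiusMM
  cosang <- (dx * spec@slipAxis[1] + dy * spec@slipAxis[2] +
             dz * spec@slipAxis[3]) / dist
  cosang[dist == 0] <- 1
  inCap <- if (spec@slipFraction <= 0) array(FALSE, gs)
           else cosang >= (1 - 2 * spec@slipFraction) - 1e-12
  # interior blend weight: 1 deep inside and throughout the slip sector,
  # ramping to 0 at the boundary in adherent sectors
  bwMM <- spec@blendWidthVox * min(spec@spacing)
  w <- pmin(1, pmax(0, (spec@tumorRadiusMM - dist) / bwMM))
  w[inCap] <- 1
  w[!inside] <- 0
  u <- array(0, c(gs, 8L, 3L))
  for (t in 0:7) {
    thetaT <- 2 * pi * t / 8
    uExt <- spec@waveAmplitudeUM * cos(karg - thetaT)
    uInt <- spec@tumorAmplitudeUM * cos(karg - thetaT + spec@tumorPhaseLag)
    uScalar <- (1 - w) * uExt + w * uInt
    for (comp in 1:3)
      u[, , , t + 1L, comp] <- spec@wavePolarization[comp] * uScalar
  }
  DisplacementField(u, spec@spacing)
}

#' Encode displacement into MR phase
#'
#' For each axis d, the positive-polarity image is
#' \eqn{\phi_{+d} = s\,u_d + \eta} and the negative-polarity image
#' \eqn{\phi_{-d} = -s\,u_d + \eta'}, with independent Gaussian phase noise
#' per voxel and offset. Reproducible for a given seed; the caller's RNG
#' stream is left untouched.
#'
#' @param disp a \linkS4class{DisplacementField}.
#' @param sensitivity encoding sensitivity in rad per displacement unit.
#' @param noiseSD phase noise standard deviation in radians.
#' @param seed integer seed.
#' @return a \linkS4class{PhaseSeries}.
#' @export
encodePhase <- function(disp, sensitivity = 1, noiseSD = 0, seed = 1L) {
  stopifnot(is(disp, "DisplacementField"))
  if (sensitivity <= 0) stop("sensitivity must be > 0")
  d <- dim(disp@u)
  phase <- array(0, c(d[1:4], 6L))
  .withSeed(seed, {
    for (comp in 1:3) {
      ud <- sensitivity * disp@u[, , , , comp, drop = FALSE]
      nEl <- length(ud)
      noisePos <- if (noiseSD > 0) array(stats::rnorm(nEl, 0, noiseSD), d[1:4]) else 0
      noiseNeg <- if (noiseSD > 0) array(stats::rnorm(nEl, 0, noiseSD), d[1:4]) else 0
      phase[, , , , 2L * comp - 1L] <- array(ud, d[1:4]) + noisePos
      phase[, , , , 2L * comp] <- array(-ud, d[1:4]) + noiseNeg
    }
  })
  PhaseSeries(phase, disp@spacing)
}

#' Simulate a complete phantom acquisition
#'
#' Builds the tumor and brain masks, slip-surface ground truth, true
#' displacement field, and noisy encoded phase for a
#' \linkS4class{PhantomSpec}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomDataset}.
#' @examples
#' ph <- simulatePhantom(phantomSpec(slipFraction = 1, seed = 3))
#' ph
#' @export
simulatePhantom <- function(spec) {
  validObject(spec)
  tmask <- .tumorMask(spec)
  bmask <- .brainMask(spec@gridShape)
  lab <- slipSurfaceLabels(tmask, spec@slipAxis, spec@slipFraction,
                           spec@tumorCenterVox, spec@spacing)
  disp <- synthesizeDisplacement(spec)
  phase <- encodePhase(disp, spec@encodingSensitivity, spec@phaseNoiseSD,
                       spec@seed)
  new("PhantomDataset", phase = phase, displacementTruth = disp,
      tumorMask = tmask, brainMask = bmask, slipLabels = lab$labels,
      trueSlipFraction = lab$realizedFraction, spec = spec)
}
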