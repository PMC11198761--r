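#' @import methods
NULL

DIRECTION_LABELS <- c("+x", "-x", "+y", "-y", "+z", "-z")
STRAIN_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

.checkSpacing <- function(spacing) {
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    return("voxel spacing must be three positive reals (mm)")
  NULL
}

#' Encoded MRE phase series
#'
#' Raw motion-encoded phase: 6 encoding directions (+x, -x, +y, -y, +z, -z)
#' by 8 phase offsets sampled over one vibration period, on a 3D voxel grid.
#' Phase is assumed already unwrapped.
#'
#' @slot data five-dimensional array \code{[nx, ny, nz, offset, direction]}
#'   of radians, with 8 offsets and 6 directions.
#' @slot spacing voxel spacing in mm along each grid axis.
#' @export
setClass("PhaseSeries",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 5L) msg <- c(msg, "phase data must be a 5D array [x,y,z,offset,direction]")
    else {
      if (d[4] != 8L) msg <- c(msg, "offsets dimension length must be 8")
      if (d[5] != 6L) msg <- c(msg, "directions dimension length must be 6")
    }
    msg <- c(msg, .checkSpacing(object@spacing))
    if (length(msg)) msg else TRUE
  })

#' Time-resolved displacement field
#'
#' Three displacement components by 8 phase offsets on a 3D grid. Units are
#' whatever the encoding sensitivity implies (micrometres for the phantom
#' generator's truth fields); the NOSS map is invariant to the overall scale.
#'
#' @slot u five-dimensional array \code{[nx, ny, nz, offset, component]}
#'   with components ordered (x, y, z).
#' @slot spacing voxel spacing in mm.
#' @export
setClass("DisplacementField",
  representation(u = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@u)
    if (length(d) != 5L) msg <- c(msg, "displacement must be a 5D array [x,y,z,offset,component]")
    else {
      if (d[4] != 8L) msg <- c(msg, "offsets dimension length must be 8")
      if (d[5] != 3L) msg <- c(msg, "components dimension length must be 3")
    }
    msg <- c(msg, .checkSpacing(object@spacing))
    if (length(msg)) msg else TRUE
  })

#' Per-voxel scalar map
#'
#' One value per voxel: mean octahedral shear strain, first-harmonic motion
#' amplitude, or the amplitude-normalized NOSS. Voxels where the map is
#' undefined (e.g. wave amplitude below the guard threshold) are \code{NA}
#' and are excluded from all downstream extrema and patch statistics.
#'
#' @slot values 3D array of non-negative reals, \code{NA} where masked.
#' @slot kind one of \code{"OSS_mean"}, \code{"amplitude"}, \code{"NOSS"}.
#' @slot spacing voxel spacing in mm.
#' @export
setClass("ScalarMap",
  representation(values = "array", kind = "character", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3D array")
    if (!object@kind %in% c("OSS_mean", "amplitude", "NOSS"))
      msg <- c(msg, "kind must be one of OSS_mean, amplitude, NOSS")
    v <- object@values
    if (any(v[is.finite(v)] < 0)) msg <- c(msg, "values must be non-negative where defined")
    msg <- c(msg, .checkSpacing(object@spacing))
    if (length(msg)) msg else TRUE
  })

#' SIR decision-function parameters
#'
#' All thresholds and constants of the slip interface recognition decision
#' function in one object. Defaults are the published operating point:
#' rectangular-partial (RP) padding of 3 pixels, 3x3 patches escalated to
#' 5x5 when the patch mean is within 0.065 of the point intensity,
#' Condition I bounds at 85% of the RP maximum and 115% of the RP minimum,
#' a Condition II threshold of 20% of the patch range, and a Condition III
#' range factor of 80% of the point intensity.
#'
#' @slot rpPad integer, RP padding in pixels beyond the ROI bounding box.
#' @slot patchDefault integer, default (odd) patch edge length.
#' @slot patchLarge integer, escalated (odd) patch edge length.
#' @slot patchEscalation numeric, escalation threshold on
#'   \code{|mean(3x3) - I(a)|}.
#' @slot cond1MaxFrac numeric in (0,1), upper-bound fraction of the RP max.
#' @slot cond1MinFrac numeric > 1 (0 disables), lower-bound fraction of the
#'   RP min.
#' @slot cond2TauFrac numeric in (0,1], fraction of the patch range defining
#'   the Condition II threshold tau.
#' @slot cond3RangeFrac numeric > 0 (may be \code{Inf} to disable), fraction
#'   of the point intensity the patch range must exceed for Condition III.
#' @slot minRoiPixels integer, minimum ROI pixels for a slice/component to
#'   be analyzed.
#' @export
setClass("SIRParams",
  representation(rpPad = "integer", patchDefault = "integer",
    patchLarge = "integer", patchEscalation = "numeric",
    cond1MaxFrac = "numeric", cond1MinFrac = "numeric",
    cond2TauFrac = "numeric", cond3RangeFrac = "numeric",
    minRoiPixels = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@rpPad < 1L) msg <- c(msg, "rpPad must be >= 1")
    if (object@patchDefault %% 2L == 0L || object@patchLarge %% 2L == 0L)
      msg <- c(msg, "patch sizes must be odd")
    if (!(object@cond1MaxFrac >= 0 && object@cond1MaxFrac <= 1))
      msg <- c(msg, "cond1MaxFrac must lie in [0, 1]")
    if (object@cond1MinFrac < 0) msg <- c(msg, "cond1MinFrac must be >= 0")
    if (!(object@cond2TauFrac > 0 && object@cond2TauFrac <= 1))
      msg <- c(msg, "cond2TauFrac must lie in (0, 1]")
    if (object@cond3RangeFrac <= 0) msg <- c(msg, "cond3RangeFrac must be > 0")
    if (object@minRoiPixels < 1L) msg <- c(msg, "minRoiPixels must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Neighborhood patch around a boundary point
#'
#' @slot center (row, col) of the boundary point in RP coordinates.
#' @slot size patch edge length, 3 or 5.
#' @slot values the size x size intensities (center included); entries
#'   outside the RP are filled by edge replication, masked entries are NA.
#' @slot stats named numeric with \code{min}, \code{max}, \code{mean} over
#'   valid (non-NA) entries.
#' @export
setClass("Patch",
  representation(center = "numeric", size = "integer", values = "matrix",
    stats = "numeric"),
  validity = function(object) {
    if (!object@size %in% c(3L, 5L)) return("patch size must be 3 or 5")
    if (!all(c("min", "max", "mean") %in% names(object@stats)))
      return("stats must contain min, max, mean")
    TRUE
  })

#' SIR adhesion result
#'
#' Per-point labels and aggregate adhesion / non-adhesion percentages for
#' one tumor, pooled over all analyzed slices (boundary point count as the
#' proxy for interface length).
#'
#' @slot points data.frame with columns \code{slice}, \code{row}, \code{col},
#'   \code{nonAdherent}, \code{condition} (one of "I","II","III","none").
#' @slot perSlice data.frame with \code{slice}, \code{nPoints},
#'   \code{nNonAdherent}.
#' @slot nonAdhesionPct pooled non-adhesion percentage in [0, 100].
#' @slot adhesionPct 100 minus \code{nonAdhesionPct}.
#' @slot conditionCounts named integer counts of fired Conditions I/II/III.
#' @slot nUnanalyzable boundary points whose own NOSS was undefined,
#'   excluded from the denominator.
#' @slot labelVolume integer 3D array: 0 non-boundary, 1 adherent,
#'   2 non-adherent, for overlay rendering.
#' @export
setClass("AdhesionResult",
  representation(points = "data.frame", perSlice = "data.frame",
    nonAdhesionPct = "numeric", adhesionPct = "numeric",
    conditionCounts = "integer", nUnanalyzable = "integer",
    labelVolume = "array"),
  validity = function(object) {
    msg <- character()
    if (abs(object@adhesionPct + object@nonAdhesionPct - 100) > 1e-9)
      msg <- c(msg, "adhesionPct + nonAdhesionPct must equal 100")
    if (object@nonAdhesionPct < 0 || object@nonAdhesionPct > 100)
      msg <- c(msg, "nonAdhesionPct must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' Synthetic phantom specification
#'
#' Parameters of the synthetic MRE acquisition: a spherical tumor inclusion
#' in a plane shear-wave field, with a spherical-cap sector of the tumor
#' surface that slips (interior oscillation discontinuous across the
#' boundary) while the remaining sector adheres (interior field blended
#' into the exterior field over a finite shell so displacement is
#' continuous).
#'
#' @slot gridShape three positive integers (voxels).
#' @slot spacing voxel spacing in mm, default (1.875, 1.875, 3).
#' @slot tumorCenterVox tumor center, 0-based voxel coordinates.
#' @slot tumorRadiusMM tumor radius in mm.
#' @slot slipFraction target fraction of tumor surface that slips, in [0,1].
#' @slot slipAxis unit 3-vector defining the spherical-cap slip sector.
#' @slot waveAmplitudeUM background wave amplitude (micrometres).
#' @slot waveLengthMM background shear wavelength (mm).
#' @slot waveDirection unit propagation direction.
#' @slot wavePolarization unit polarization, orthogonal to the direction.
#' @slot tumorAmplitudeUM interior oscillation amplitude (micrometres).
#' @slot tumorPhaseLag interior phase lag (radians).
#' @slot blendWidthVox transition-shell width in voxels for adherent sectors.
#' @slot encodingSensitivity phase per displacement (rad/um).
#' @slot phaseNoiseSD Gaussian phase noise SD (radians).
#' @slot nOffsets number of phase offsets (8).
#' @slot seed integer RNG seed for the phase noise.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
    tumorCenterVox = "numeric", tumorRadiusMM = "numeric",
    slipFraction = "numeric", slipAxis = "numeric",
    waveAmplitudeUM = "numeric", waveLengthMM = "numeric",
    waveDirection = "numeric", wavePolarization = "numeric",
    tumorAmplitudeUM = "numeric", tumorPhaseLag = "numeric",
    blendWidthVox = "numeric", encodingSensitivity = "numeric",
    phaseNoiseSD = "numeric", nOffsets = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    msg <- c(msg, .checkSpacing(object@spacing))
    if (length(object@gridShape) != 3L || any(object@gridShape < 3L))
      msg <- c(msg, "gridShape must be three integers >= 3")
    unit <- function(v) abs(sqrt(sum(v^2)) - 1) <= 1e-9
    if (!unit(object@slipAxis)) msg <- c(msg, "slipAxis must be a unit vector")
    if (!unit(object@waveDirection)) msg <- c(msg, "waveDirection must be a unit vector")
    if (!unit(object@wavePolarization)) msg <- c(msg, "wavePolarization must be a unit vector")
    if (abs(sum(object@waveDirection * object@wavePolarization)) > 1e-9)
      msg <- c(msg, "polarization must be orthogonal to direction")
    if (object@slipFraction < 0 || object@slipFraction > 1)
      msg <- c(msg, "slipFraction must lie in [0, 1]")
    if (object@tumorRadiusMM <= 0) msg <- c(msg, "tumorRadiusMM must be > 0")
    if (object@blendWidthVox <= 0) msg <- c(msg, "blendWidthVox must be > 0")
    if (object@encodingSensitivity <= 0) msg <- c(msg, "encodingSensitivity must be > 0")
    if (object@phaseNoiseSD < 0) msg <- c(msg, "phaseNoiseSD must be >= 0")
    if (object@waveAmplitudeUM <= 0 || object@waveLengthMM <= 0)
      msg <- c(msg, "wave amplitude and wavelength must be > 0")
    if (object@nOffsets != 8L) msg <- c(msg, "nOffsets must be 8")
    # tumor sphere must fit inside the grid with >= 6 voxels of margin
    if (length(msg) == 0L) {
      for (a in 1:3) {
        rv <- object@tumorRadiusMM / object@spacing[a]
        lo <- object@tumorCenterVox[a] - rv
        hi <- object@tumorCenterVox[a] + rv
        if (lo < 6 || hi > (object@gridShape[a] - 1) - 6) {
          msg <- c(msg, "tumor sphere must fit inside the grid with >= 6 voxels margin")
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Synthetic phantom dataset
#'
#' A complete synthetic acquisition with ground truth: encoded phase,
#' the true displacement field, tumor and brain masks, and the per
#' surface-voxel slip labels with the realized slip-surface fraction.
#'
#' @slot phase a \linkS4class{PhaseSeries}.
#' @slot displacementTruth a \linkS4class{DisplacementField}.
#' @slot tumorMask logical 3D array.
#' @slot brainMask logical 3D array.
#' @slot slipLabels data.frame (\code{i}, \code{j}, \code{k} 1-based voxel
#'   indices of tumor surface voxels; \code{slip} logical).
#' @slot trueSlipFraction realized surface-area fraction in [0, 1].
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("PhantomDataset",
  representation(phase = "PhaseSeries", displacementTruth = "DisplacementField",
    tumorMask = "array", brainMask = "array", slipLabels = "data.frame",
    trueSlipFraction = "numeric", spec = "PhantomSpec"),
  validity = function(object) {
    msg <- character()
    if (any(object@tumorMask & !object@brainMask))
      msg <- c(msg, "tumor mask must be contained in the brain mask")
    if (object@trueSlipFraction < 0 || object@trueSlipFraction > 1)
      msg <- c(msg, "trueSlipFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Boundary-entropy baseline parameters
#'
#' Parameters of the boundary NOSS-difference entropy metric: sampling
#' depth on each side of the boundary along the outward normal, and the
#' histogram used for the Shannon entropy of the differences.
#'
#' @slot normalDepthVox sampling depth in voxels on each side (>= 1).
#' @slot nBins number of histogram bins (>= 2).
#' @slot binRange fixed histogram range on standardized NOSS differences.
#' @export
setClass("EntropyParams",
  representation(normalDepthVox = "integer", nBins = "integer",
    binRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@normalDepthVox < 1L) msg <- c(msg, "normalDepthVox must be >= 1")
    if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
    if (length(object@binRange) != 2L || object@binRange[1] >= object@binRange[2])
      msg <- c(msg, "binRange must be an increasing pair")
    if (length(msg)) msg else TRUE
  })
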