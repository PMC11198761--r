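#' @rdname PhaseSeries-class
#' @param data,u,values array payloads (see class slots)
#' @param spacing voxel spacing in mm
#' @export
PhaseSeries <- function(data, spacing) {
  new("PhaseSeries", data = data, spacing = as.numeric(spacing))
}

#' @rdname DisplacementField-class
#' @export
DisplacementField <- function(u, spacing) {
  new("DisplacementField", u = u, spacing = as.numeric(spacing))
}

#' @rdname ScalarMap-class
#' @param kind map kind: "OSS_mean", "amplitude" or "NOSS"
#' @export
ScalarMap <- function(values, kind, spacing) {
  new("ScalarMap", values = values, kind = kind, spacing = as.numeric(spacing))
}

#' Construct SIR decision-function parameters
#'
#' @param rpPad RP padding in pixels (default 3; raise to 5 for very
#'   irregular boundaries).
#' @param patchDefault default patch edge length (3).
#' @param patchLarge escalated patch edge length (5).
#' @param patchEscalation escalation threshold (default 0.065).
#' @param cond1MaxFrac Condition I upper-bound fraction of the RP maximum
#'   (default 0.85).
#' @param cond1MinFrac Condition I lower-bound fraction of the RP minimum
#'   (default 1.15; 0 disables the lower branch).
#' @param cond2TauFrac Condition II fraction of the patch range (default
#'   0.20).
#' @param cond3RangeFrac Condition III fraction of the point intensity
#'   (default 0.80; \code{Inf} disables).
#' @param minRoiPixels minimum ROI pixels per slice/component (default 5).
#' @return a \linkS4class{SIRParams} object.
#' @examples
#' sirParams()
#' sirParams(cond2TauFrac = 0.25)
#' @export
sirParams <- function(rpPad = 3L, patchDefault = 3L, patchLarge = 5L,
                      patchEscalation = 0.065, cond1MaxFrac = 0.85,
                      cond1MinFrac = 1.15, cond2TauFrac = 0.20,
                      cond3RangeFrac = 0.80, minRoiPixels = 5L) {
  new("SIRParams", rpPad = as.integer(rpPad),
    patchDefault = as.integer(patchDefault),
    patchLarge = as.integer(patchLarge),
    patchEscalation = patchEscalation, cond1MaxFrac = cond1MaxFrac,
    cond1MinFrac = cond1MinFrac, cond2TauFrac = cond2TauFrac,
    cond3RangeFrac = cond3RangeFrac, minRoiPixels = as.integer(minRoiPixels))
}

#' Construct boundary-entropy parameters
#'
#' @param normalDepthVox sampling depth in voxels on each side of the
#'   boundary (default 2).
#' @param nBins histogram bins (default 32).
#' @param binRange histogram range on standardized NOSS differences
#'   (default c(-1, 1)).
#' @return an \linkS4class{EntropyParams} object.
#' @export
entropyParams <- function(normalDepthVox = 2L, nBins = 32L,
                          binRange = c(-1, 1)) {
  new("EntropyParams", normalDepthVox = as.integer(normalDepthVox),
    nBins = as.integer(nBins), binRange = as.numeric(binRange))
}

#' Voxel spacing accessor
#' @param x an object with a spacing slot.
#' @return numeric(3) voxel spacing in mm.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "PhaseSeries", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ScalarMap", function(x) x@spacing)

#' Map values accessor
#' @param x a ScalarMap.
#' @return the 3D array of values (NA where masked).
#' @export
mapValues <- function(x) x@values

#' Map kind accessor
#' @param x a ScalarMap.
#' @export
mapKind <- function(x) x@kind

#' Phase data accessor
#' @param x a PhaseSeries.
#' @return 5D array [x,y,z,offset,direction].
#' @export
phaseData <- function(x) x@data

#' Displacement accessor
#' @param x a DisplacementField.
#' @return 5D array [x,y,z,offset,component].
#' @export
displacement <- function(x) x@u

#' Pooled non-adhesion percentage
#' @param x an AdhesionResult.
#' @export
nonAdhesionPct <- function(x) x@nonAdhesionPct

#' Pooled adhesion percentage
#' @param x an AdhesionResult.
#' @export
adhesionPct <- function(x) x@adhesionPct

#' Counts of fired SIR conditions
#' @param x an AdhesionResult.
#' @export
conditionCounts <- function(x) x@conditionCounts

#' Per-point SIR labels
#' @param x an AdhesionResult.
#' @return data.frame with slice, row, col, nonAdherent, condition.
#' @export
pointLabels <- function(x) x@points

#' Per-slice tallies
#' @param x an AdhesionResult.
#' @export
perSlice <- function(x) x@perSlice

#' Boundary label overlay volume
#' @param x an AdhesionResult.
#' @return integer array: 0 non-boundary, 1 adherent, 2 non-adherent.
#' @export
labelVolume <- function(x) x@labelVolume

#' Phantom accessors
#' @param x a PhantomDataset.
#' @name phantom-accessors
NULL

#' @rdname phantom-accessors
#' @export
tumorMask <- function(x) x@tumorMask
#' @rdname phantom-accessors
#' @export
brainMask <- function(x) x@brainMask
#' @rdname phantom-accessors
#' @export
phantomPhase <- function(x) x@phase
#' @rdname phantom-accessors
#' @export
displacementTruth <- function(x) x@displacementTruth
#' @rdname phantom-accessors
#' @export
slipLabels <- function(x) x@slipLabels
#' @rdname phantom-accessors
#' @export
trueSlipFraction <- function(x) x@trueSlipFraction

setMethod("show", "PhaseSeries", function(object) {
  d <- dim(object@data)
  cat("PhaseSeries: grid ", paste(d[1:3], collapse = " x "),
      ", ", d[4], " offsets, ", d[5], " directions (",
      paste(DIRECTION_LABELS, collapse = ", "), ")\n", sep = "")
  cat("  spacing (mm): ", paste(format(object@spacing), collapse = " x "), "\n", sep = "")
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@u)
  cat("DisplacementField: grid ", paste(d[1:3], collapse = " x "),
      ", ", d[4], " offsets, components (x, y, z)\n", sep = "")
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@values
  cat("ScalarMap <", object@kind, ">: grid ",
      paste(dim(v), collapse = " x "), "\n", sep = "")
  cat("  defined voxels: ", sum(!is.na(v)), " / ", length(v),
      "; range [", format(suppressWarnings(min(v, na.rm = TRUE)), digits = 4),
      ", ", format(suppressWarnings(max(v, na.rm = TRUE)), digits = 4), "]\n",
      sep = "")
})

setMethod("show", "SIRParams", function(object) {
  cat("SIRParams:\n")
  cat("  RP pad:", object@rpPad, " patch:", object@patchDefault, "->",
      object@patchLarge, " escalation:", object@patchEscalation, "\n")
  cat("  Condition I: >", object@cond1MaxFrac, "* RPmax  or  <",
      object@cond1MinFrac, "* RPmin\n")
  cat("  Condition II tau:", object@cond2TauFrac, "* patch range;",
      "Condition III:", object@cond3RangeFrac, "* point intensity\n")
  cat("  min ROI pixels per slice:", object@minRoiPixels, "\n")
})

setMethod("show", "AdhesionResult", function(object) {
  cat("AdhesionResult: ", nrow(object@points), " boundary points over ",
      nrow(object@perSlice), " slices\n", sep = "")
  cat(sprintf("  non-adhesion: %.2f%%  adhesion: %.2f%%\n",
              object@nonAdhesionPct, object@adhesionPct))
  cc <- object@conditionCounts
  cat("  fired conditions  I:", cc[["I"]], " II:", cc[["II"]],
      " III:", cc[["III"]], "\n")
  if (object@nUnanalyzable > 0L)
    cat("  unanalyzable points (undefined NOSS):", object@nUnanalyzable, "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: grid ", paste(object@gridShape, collapse = " x "),
      " @ (", paste(format(object@spacing), collapse = ", "), ") mm\n", sep = "")
  cat("  tumor: radius ", object@tumorRadiusMM, " mm at voxel (",
      paste(format(object@tumorCenterVox), collapse = ", "),
      "), slip fraction ", object@slipFraction, "\n", sep = "")
  cat("  wave: A =", object@waveAmplitudeUM, "um, lambda =",
      object@waveLengthMM, "mm; tumor A =", object@tumorAmplitudeUM,
      "um, lag =", format(object@tumorPhaseLag, digits = 4), "rad\n")
})

setMethod("show", "PhantomDataset", function(object) {
  cat("PhantomDataset: ", sum(object@tumorMask), " tumor voxels, ",
      nrow(object@slipLabels), " surface voxels, realized slip fraction ",
      format(object@trueSlipFraction, digits = 4), "\n", sep = "")
})
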