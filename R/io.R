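#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 volume, returning the voxel data, the voxel spacing
#' from the header, and the image object so the affine and header round
#' trip untouched on write. Optionally checks the grid against a reference
#' shape.
#'
#' @param path path to a .nii / .nii.gz file.
#' @param referenceShape optional integer vector; a mismatch of the first
#'   three dimensions raises an error listing both shapes.
#' @return list with \code{data} (array), \code{spacing} (mm, first three
#'   pixdims), and \code{image} (the RNifti image for affine passthrough).
#' @export
readVolume <- function(path, referenceShape = NULL) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  spacing <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  if (!is.null(referenceShape)) {
    got <- dim(data)[1:3]
    ref <- referenceShape[1:3]
    if (!all(got == ref))
      stop(sprintf("grid mismatch for %s: got %s, expected %s", path,
                   paste(got, collapse = "x"), paste(ref, collapse = "x")))
  }
  list(data = data, spacing = as.numeric(spacing), image = img)
}

#' Write a NIfTI volume
#'
#' @param data numeric or integer array (3D or 4D).
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel spacing in mm for the first three dimensions.
#' @param reference optional RNifti image whose header/affine to reuse.
#' @return the path, invisibly.
#' @export
writeVolume <- function(data, path, spacing = c(1, 1, 1), reference = NULL) {
  if (!is.null(reference)) {
    img <- RNifti::asNifti(data, reference = reference)
  } else {
    img <- RNifti::asNifti(data)
    pd <- RNifti::pixdim(img)
    pd[seq_len(min(3L, length(pd)))] <- spacing[seq_len(min(3L, length(pd)))]
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' One 4D NIfTI per encoding direction (4th dimension = 8 offsets), uint8
#' masks, and a JSON file with the slip-surface ground truth, realized
#' fraction, and the full generating parameter set.
#'
#' @param ph a \linkS4class{PhantomDataset}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writePhantom <- function(ph, dir) {
  stopifnot(is(ph, "PhantomDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- ph@phase@spacing
  paths <- c()
  dirTags <- c("xp", "xn", "yp", "yn", "zp", "zn")
  for (d in 1:6) {
    p <- file.path(dir, sprintf("phase_%s.nii.gz", dirTags[d]))
    writeVolume(ph@phase@data[, , , , d], p, sp)
    paths[paste0("phase_", dirTags[d])] <- p
  }
  pTum <- file.path(dir, "tumor_mask.nii.gz")
  writeVolume(array(as.integer(ph@tumorMask), dim(ph@tumorMask)), pTum, sp)
  pBr <- file.path(dir, "brain_mask.nii.gz")
  writeVolume(array(as.integer(ph@brainMask), dim(ph@brainMask)), pBr, sp)
  truth <- list(
    realized_slip_fraction = ph@trueSlipFraction,
    surface_voxels = ph@slipLabels,
    parameters = .specAsList(ph@spec))
  pJ <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, pJ, auto_unbox = TRUE, digits = NA)
  paths[c("tumor_mask", "brain_mask", "truth")] <- c(pTum, pBr, pJ)
  invisible(paths)
}

.specAsList <- function(spec) {
  list(grid_shape = spec@gridShape, voxel_spacing_mm = spec@spacing,
       tumor_center_vox = spec@tumorCenterVox,
       tumor_radius_mm = spec@tumorRadiusMM,
       slip_fraction = spec@slipFraction, slip_axis = spec@slipAxis,
       wave_amplitude_um = spec@waveAmplitudeUM,
       wave_length_mm = spec@waveLengthMM,
       wave_direction = spec@waveDirection,
       wave_polarization = spec@wavePolarization,
       tumor_amplitude_um = spec@tumorAmplitudeUM,
       tumor_phase_lag_rad = spec@tumorPhaseLag,
       blend_width_vox = spec@blendWidthVox,
       encoding_sensitivity_rad_per_um = spec@encodingSensitivity,
       phase_noise_sd_rad = spec@phaseNoiseSD,
       n_offsets = spec@nOffsets, seed = spec@seed)
}

.paramsAsList <- function(params) {
  list(rp_pad_vox = params@rpPad, patch_size_default = params@patchDefault,
       patch_size_large = params@patchLarge,
       patch_escalation_threshold = params@patchEscalation,
       cond1_max_frac = params@cond1MaxFrac,
       cond1_min_frac = params@cond1MinFrac,
       cond2_tau_frac = params@cond2TauFrac,
       cond3_range_frac = params@cond3RangeFrac,
       min_roi_pixels_per_slice = params@minRoiPixels)
}

#' Load a six-file phase set
#'
#' Reads the per-direction 4D phase volumes written by
#' \code{\link{writePhantom}} (or any co-registered set in the same
#' +x, -x, +y, -y, +z, -z order) into a \linkS4class{PhaseSeries}. All
#' grids must match or an error is raised.
#'
#' @param paths character(6) of NIfTI paths in direction order.
#' @return a \linkS4class{PhaseSeries}.
#' @export
readPhaseSet <- function(paths) {
  if (length(paths) != 6L) stop("expected 6 phase volumes (+x,-x,+y,-y,+z,-z)")
  first <- readVolume(paths[1])
  d <- dim(first$data)
  if (length(d) != 4L || d[4] != 8L)
    stop("each phase volume must be 4D with 8 offsets")
  phase <- array(0, c(d, 6L))
  phase[, , , , 1L] <- first$data
  for (i in 2:6) {
    v <- readVolume(paths[i], referenceShape = d[1:3])
    if (!identical(dim(v$data), d))
      stop(sprintf("grid mismatch for %s: got %s, expected %s", paths[i],
                   paste(dim(v$data), collapse = "x"),
                   paste(d, collapse = "x")))
    phase[, , , , i] <- v$data
  }
  PhaseSeries(phase, first$spacing)
}

#' Export an SIR adhesion result to disk
#'
#' Writes the aggregate result (including the full parameter set used) as
#' JSON, the per-point labels as CSV, and the boundary label overlay as a
#' NIfTI volume.
#'
#' @param res an \linkS4class{AdhesionResult}.
#' @param dir output directory.
#' @param params the \linkS4class{SIRParams} used (embedded in the JSON).
#' @param spacing voxel spacing for the overlay volume.
#' @param seed optional seed to record.
#' @return named character vector of written paths, invisibly.
#' @export
writeAdhesionResult <- function(res, dir, params = sirParams(),
                                spacing = c(1, 1, 1), seed = NULL) {
  stopifnot(is(res, "AdhesionResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    non_adhesion_pct = res@nonAdhesionPct,
    adhesion_pct = res@adhesionPct,
    n_points = nrow(res@points),
    n_unanalyzable = res@nUnanalyzable,
    condition_counts = as.list(res@conditionCounts),
    per_slice = res@perSlice,
    parameters = .paramsAsList(params))
  if (!is.null(seed)) out$seed <- seed
  pJ <- file.path(dir, "adhesion_result.json")
  jsonlite::write_json(out, pJ, auto_unbox = TRUE, digits = NA)
  pC <- file.path(dir, "point_labels.csv")
  utils::write.csv(res@points, pC, row.names = FALSE)
  pN <- file.path(dir, "label_overlay.nii.gz")
  writeVolume(res@labelVolume, pN, spacing)
  invisible(c(json = pJ, csv = pC, overlay = pN))
}
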