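#' Run a configured end-to-end analysis
#'
#' Binds the stages into one reproducible run: simulate (or load) an
#' acquisition, compute the NOSS map, run slip interface recognition and
#' optionally the boundary-entropy baseline, and write all results plus a
#' machine-readable provenance record (full parameter set, seed, package
#' version) to the output directory. Identical config and seed give
#' identical outputs.
#'
#' @param config a named list with elements:
#'   \describe{
#'     \item{phantom}{a \linkS4class{PhantomSpec}, or a list of arguments
#'       for \code{\link{phantomSpec}} (used when no phase paths given).}
#'     \item{phasePaths}{character(6) NIfTI paths (+x,-x,+y,-y,+z,-z).}
#'     \item{tumorMaskPath, brainMaskPath}{NIfTI mask paths (required with
#'       phasePaths).}
#'     \item{sensitivity}{encoding sensitivity, default 1.}
#'     \item{sirParams}{a \linkS4class{SIRParams} (default
#'       \code{sirParams()}).}
#'     \item{entropyParams}{an \linkS4class{EntropyParams}; include to run
#'       the baseline.}
#'     \item{outputDir}{output directory.}
#'     \item{seed}{integer seed (overrides the phantom spec's seed).}
#'   }
#' @return list with \code{sir} (\linkS4class{AdhesionResult}),
#'   \code{baseline} (or NULL), \code{maps}, and \code{paths} of written
#'   artifacts.
#' @export
runPipeline <- function(config) {
  outDir <- config$outputDir
  if (is.null(outDir)) stop("config$outputDir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- if (is.null(config$sirParams)) sirParams() else config$sirParams
  sens <- if (is.null(config$sensitivity)) 1 else config$sensitivity
  paths <- c()
  if (!is.null(config$phasePaths)) {
    for (p in c(config$phasePaths, config$tumorMaskPath, config$brainMaskPath))
      if (!is.null(p) && !file.exists(p)) stop("missing input path: ", p)
    phase <- readPhaseSet(config$phasePaths)
    if (is.null(config$tumorMaskPath)) stop("tumorMaskPath is required")
    tmask <- readVolume(config$tumorMaskPath,
                        referenceShape = dim(phase@data)[1:3])$data > 0
    bmask <- if (is.null(config$brainMaskPath)) NULL
             else readVolume(config$brainMaskPath,
                             referenceShape = dim(phase@data)[1:3])$data > 0
  } else {
    spec <- config$phantom
    if (is.null(spec)) spec <- phantomSpec(seed = seed)
    else if (is.list(spec)) spec <- do.call(phantomSpec, spec)
    spec@seed <- seed
    ph <- simulatePhantom(spec)
    paths <- c(paths, writePhantom(ph, file.path(outDir, "phantom")))
    phase <- ph@phase
    tmask <- ph@tumorMask
    bmask <- ph@brainMask
  }
  maps <- computeNOSS(phase, sensitivity = sens, mask = bmask)
  sp <- phase@spacing
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(maps$noss@values, file.path(outDir, "noss.nii.gz"), sp)
  writeVolume(maps$amplitude@values, file.path(outDir, "amplitude.nii.gz"), sp)
  writeVolume(maps$ossMean@values, file.path(outDir, "oss_mean.nii.gz"), sp)
  res <- runSIR(maps$noss, tmask, params)
  paths <- c(paths, writeAdhesionResult(res, outDir, params, sp, seed))
  baseline <- NULL
  if (!is.null(config$entropyParams)) {
    baseline <- runEntropyBaseline(maps$noss, tmask, config$entropyParams,
                                   params)
    jsonlite::write_json(
      list(entropy_bits = baseline$entropy, n_values = baseline$nValues,
           normal_depth_vox = config$entropyParams@normalDepthVox,
           n_bins = config$entropyParams@nBins, seed = seed),
      file.path(outDir, "baseline_entropy.json"), auto_unbox = TRUE,
      digits = NA)
  }
  prov <- list(package = "slipsir",
               version = as.character(utils::packageVersion("slipsir")),
               seed = seed, sensitivity = sens,
               sir_params = .paramsAsList(params))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  list(sir = res, baseline = baseline, maps = maps, paths = paths)
}
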