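#' @include AllClasses.R io.R
NULL

#' Construct a validated pipeline configuration
#'
#' @param phantom a [PhantomConfig-class].
#' @param tissue a [TissueProperties-class].
#' @param frameTimes frame times, s.
#' @param reduction undersampling factor R (1 = fully sampled).
#' @param nACS autocalibration lines.
#' @param kxHalfWidth,kyHalfWidth kernel stencil extents.
#' @param ssimWindow SSIM window side.
#' @param positions cross-section positions, mm (empty = automatic: one
#'   per slice, excluding the corpus-adjacent end).
#' @param seed master seed (drives the phantom noise).
#' @param outDir output directory; "" returns results without writing.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(phantom = phantomConfig(),
                      tissue = tissueProperties(),
                      frameTimes = defaultFrameTimes(),
                      reduction = 3L, nACS = 12L,
                      kxHalfWidth = 2L, kyHalfWidth = 2L,
                      ssimWindow = 7L, positions = numeric(),
                      seed = 1L, outDir = "") {
  new("RunConfig", phantom = phantom, tissue = tissue,
      frameTimes = as.numeric(frameTimes),
      reduction = as.integer(reduction), nACS = as.integer(nACS),
      kxHalfWidth = as.integer(kxHalfWidth),
      kyHalfWidth = as.integer(kyHalfWidth),
      ssimWindow = as.integer(ssimWindow),
      positions = as.numeric(positions), seed = as.integer(seed),
      outDir = outDir)
}

.defaultPositions <- function(config) {
  g <- config@grid; dz <- config@voxelSize[3L]
  zc <- (seq_len(g[3L]) - 0.5) * dz
  zc[seq_len(max(1L, g[3L] - 1L))]
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full simulate / undersample / reconstruct / evaluate pipeline
#'
#' Generates the dynamic phantom and its fully sampled k-space,
#' retrospectively undersamples it with the time-interleaved pattern,
#' calibrates and applies the k-t interpolation kernels, reconstructs
#' magnitude images, and computes image-quality metrics against the fully
#' sampled reference and motility metrics on both series. Deterministic
#' given the seed. When `outDir` is set, images, `metrics.json`,
#' `motility.json`, the calibration report and a run manifest are written
#' there.
#'
#' @param config a [RunConfig-class].
#' @return a list with elements `reference`, `recon` ([ImageSeries-class]),
#'   `kernels`, `calibration` (report), `metrics`, `motility`
#'   (reconstruction and reference), and `manifest`.
#' @export
runPipeline <- function(config) {
  validObject(config)
  ph <- config@phantom
  ph@seed <- config@seed
  reference <- .stage("simulate",
                      generatePhantom(ph, config@tissue, config@frameTimes))
  kfull <- .stage("forward-model", phantomToKspace(reference))
  hints <- antralAxisTruth(ph)
  hints <- hints[c(1L, nrow(hints)), ]
  positions <- if (length(config@positions)) config@positions else
    .defaultPositions(ph)

  if (config@reduction > 1L) {
    pattern <- samplingPattern(nPE = dim(kfull@data)[2L],
                               nACS = config@nACS,
                               reduction = config@reduction)
    kunder <- .stage("undersample", applyMask(kfull, pattern))
    geom <- ktKernelGeometry(config@reduction,
                             kxHalfWidth = config@kxHalfWidth,
                             kyHalfWidth = config@kyHalfWidth)
    cal <- .stage("calibrate", calibrateKernels(kunder, geom))
    kfilled <- .stage("interpolate", interpolateKspace(kunder, cal$kernels))
    recon <- .stage("reconstruct", reconstructImages(kfilled))
    kernels <- cal$kernels
    calreport <- cal$report
  } else {
    recon <- .stage("reconstruct", reconstructImages(kfull))
    kernels <- NULL
    calreport <- NULL
  }

  metrics <- .stage("evaluate",
                    imageQuality(recon, reference,
                                 ssimWindow = config@ssimWindow))
  motRef <- .stage("motility-reference",
                   measureMotility(reference, hints = hints,
                                   positions = positions))
  motRec <- .stage("motility-recon",
                   measureMotility(recon, hints = hints,
                                   positions = positions))
  manifest <- list(seed = config@seed, reduction = config@reduction,
                   nACS = config@nACS,
                   grid = ph@grid, nFrames = length(config@frameTimes),
                   positions = positions)
  res <- list(reference = reference, recon = recon, kernels = kernels,
              calibration = calreport, metrics = metrics,
              motility = list(recon = motRec, reference = motRef),
              manifest = manifest)
  if (nzchar(config@outDir)) .writeRunOutputs(res, config)
  res
}

.motilityAsList <- function(m) {
  list(amplitude = m@amplitude, amplitudeRadius = m@amplitudeRadius,
       frequency = m@frequency, velocity = m@velocity, volume = m@volume)
}

.writeRunOutputs <- function(res, config) {
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config@outDir, f)
  writeImageSeries(res$reference, out("reference.nii"))
  writeImageSeries(res$recon, out("recon.nii"))
  jsonlite::write_json(res$metrics, out("metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(res$motility, .motilityAsList),
                       out("motility.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$calibration))
    jsonlite::write_json(res$calibration, out("calibration.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(res$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Sweep the reduction factor
#'
#' Re-runs undersampling, calibration, interpolation and reconstruction of
#' the same phantom for several reduction factors and tabulates RE, SSIM
#' and PSNR against the fully sampled reference (the reduction-factor
#' degradation table of the retrospective evaluation).
#'
#' @param config a [RunConfig-class]; its `reduction` slot is ignored.
#' @param reductions integer vector of reduction factors (1 allowed).
#' @return data.frame with columns `R`, `re`, `ssim`, `psnr`.
#' @export
sweepReduction <- function(config, reductions = c(2L, 3L, 11L)) {
  validObject(config)
  ph <- config@phantom
  ph@seed <- config@seed
  reference <- generatePhantom(ph, config@tissue, config@frameTimes)
  kfull <- phantomToKspace(reference)
  rows <- lapply(reductions, function(R) {
    recon <- if (R > 1L) {
      pattern <- samplingPattern(nPE = dim(kfull@data)[2L],
                                 nACS = config@nACS, reduction = R)
      kunder <- applyMask(kfull, pattern)
      geom <- ktKernelGeometry(R, kxHalfWidth = config@kxHalfWidth,
                               kyHalfWidth = config@kyHalfWidth)
      cal <- calibrateKernels(kunder, geom)
      reconstructImages(interpolateKspace(kunder, cal$kernels))
    } else reconstructImages(kfull)
    q <- imageQuality(recon, reference, ssimWindow = config@ssimWindow)
    data.frame(R = R, re = q$re, ssim = q$ssim, psnr = q$psnr)
  })
  do.call(rbind, rows)
}
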