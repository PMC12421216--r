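#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
setMethod("intensities", "ImageSeries", function(object) object@values)

#' @rdname accessors
setMethod("kspaceData", "KSpaceSeries", function(object) object@data)

#' @rdname accessors
setMethod("samplingMask", "KSpaceSeries", function(object) object@mask)

#' @rdname accessors
setMethod("voxelSize", "ImageSeries", function(object) object@voxelSize)

#' @rdname accessors
setMethod("voxelSize", "KSpaceSeries", function(object) object@voxelSize)

#' @rdname accessors
setMethod("frameTimes", "ImageSeries", function(object) object@frameTimes)

#' @rdname accessors
setMethod("frameTimes", "KSpaceSeries", function(object) object@frameTimes)

#' @rdname accessors
setMethod("nFrames", "ImageSeries", function(object) dim(object@values)[4L])

#' @rdname accessors
setMethod("nFrames", "KSpaceSeries", function(object) dim(object@data)[4L])

#' @rdname accessors
setMethod("areas", "AreaTimeSeries", function(object) object@areas)

#' @rdname accessors
setMethod("frameTimes", "AreaTimeSeries", function(object) object@times)

#' @rdname accessors
setMethod("peakIndices", "AreaTimeSeries", function(object) object@peaks)

#' @rdname accessors
setMethod("valleyIndices", "AreaTimeSeries",
          function(object) object@valleys)

#' @rdname accessors
setMethod("reduction", "SamplingPattern", function(object) object@reduction)

#' @rdname accessors
setMethod("reduction", "KTKernelSet", function(object) object@reduction)

#' @rdname accessors
#' @details `acsLines` returns the 1-based indices of the autocalibration
#'   block, centred so that the DC line (`floor(nPE/2) + 1`) is the
#'   upper-middle ACS line when `nACS` is even.
setMethod("acsLines", "SamplingPattern", function(object) {
  if (object@nACS == 0L) return(integer())
  dc <- object@nPE %/% 2L + 1L          # centred DC line, 1-based
  lo <- dc - object@nACS %/% 2L
  seq.int(lo, length.out = object@nACS)
})

setMethod("show", "ImageSeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageSeries: %d x %d x %d slices x %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size %s mm; t = %.3g .. %.3g s\n",
              paste(signif(object@voxelSize, 3), collapse = " x "),
              object@frameTimes[1], object@frameTimes[length(object@frameTimes)]))
  cat(sprintf("  intensity range [%.4g, %.4g]; provenance: %s\n",
              min(object@values), max(object@values),
              if (length(object@provenance)) object@provenance else "?"))
})

setMethod("show", "KSpaceSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("KSpaceSeries: %d x %d x %d slices x %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  sampled lines: %.1f%%\n", 100 * mean(object@mask)))
})

setMethod("show", "SamplingPattern", function(object) {
  cat(sprintf(
    "SamplingPattern: %d PE lines, %d ACS, R = %d (%s phase rule)\n",
    object@nPE, object@nACS, object@reduction,
    if (length(object@phaseOffsets)) "custom" else "frame mod R"))
})

setMethod("show", "KTKernelSet", function(object) {
  cat(sprintf("KTKernelSet: R = %d, %d shape(s)%s\n", object@reduction,
              length(object@shapes),
              if (object@calibrated) ", calibrated" else " (weights unset)"))
  cat(sprintf("  kx half-width %d, |dky| <= %d, window %d frames\n",
              object@kxHalfWidth, object@kyHalfWidth, object@tWindow))
})

setMethod("show", "MotilityMetrics", function(object) {
  cat("MotilityMetrics:\n")
  cat(sprintf("  amplitude (area occlusion)   %.3f\n", object@amplitude))
  cat(sprintf("  amplitude (radius-equiv.)    %.3f\n", object@amplitudeRadius))
  cat(sprintf("  frequency                    %.2f cpm\n", object@frequency))
  cat(sprintf("  propagation velocity         %.3f mm/s\n", object@velocity))
  cat(sprintf("  time-averaged volume         %.3f mL\n", object@volume))
})

setMethod("show", "AcquisitionSchedule", function(object) {
  n <- length(object@volumeStart)
  cat(sprintf("AcquisitionSchedule: %d volume(s)%s\n", n,
              if (object@truncated) " (truncated)" else ""))
  if (n)
    cat(sprintf("  effective resolution %.3g s (max over volumes)\n",
                max(object@effectiveResolution, na.rm = TRUE)))
})
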