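#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a time-interleaved sampling pattern
#'
#' @param nPE number of phase-encode lines.
#' @param nACS number of fully sampled central autocalibration lines.
#' @param reduction peripheral reduction factor R.
#' @param phaseOffsets optional per-frame phase offsets in `0..R-1`
#'   (recycled over frames); `NULL` selects the default rule, offset
#'   `(frame - 1) mod R`, under which the union of R consecutive frames
#'   covers every line.
#' @return a validated [SamplingPattern-class].
#' @export
samplingPattern <- function(nPE, nACS = 12L, reduction = 3L,
                            phaseOffsets = NULL) {
  new("SamplingPattern", nPE = as.integer(nPE), nACS = as.integer(nACS),
      reduction = as.integer(reduction),
      phaseOffsets = as.integer(phaseOffsets %||% integer()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.phaseOffset <- function(pattern, frameIndex) {
  if (length(pattern@phaseOffsets))
    pattern@phaseOffsets[(frameIndex - 1L) %% length(pattern@phaseOffsets) + 1L]
  else (frameIndex - 1L) %% pattern@reduction
}

#' Build the phase-encode line mask for one frame
#'
#' ACS lines are always sampled; a peripheral line with 0-based index `j`
#' is sampled iff `j mod R` equals the frame's phase offset.
#'
#' @param pattern a [SamplingPattern-class].
#' @param frameIndex 1-based frame index.
#' @return logical vector of length `nPE`; `TRUE` = line acquired.
#' @export
buildMask <- function(pattern, frameIndex) {
  validObject(pattern)
  if (frameIndex < 1L) .stopf("frameIndex must be >= 1")
  j <- seq_len(pattern@nPE) - 1L            # 0-based line index
  m <- (j %% pattern@reduction) == .phaseOffset(pattern, frameIndex)
  m[acsLines(pattern)] <- TRUE
  m
}

#' Retrospectively undersample a fully sampled k-space series
#'
#' Zeroes the phase-encode lines not selected by the pattern and records
#' them in the mask; sampled lines are copied bit-identically, so applying
#' the same pattern twice is idempotent.
#'
#' @param kspace a fully sampled [KSpaceSeries-class].
#' @param pattern a [SamplingPattern-class] with `nPE` equal to the ky
#'   dimension.
#' @return an undersampled [KSpaceSeries-class].
#' @export
applyMask <- function(kspace, pattern) {
  stopifnot(is(kspace, "KSpaceSeries"))
  validObject(pattern)
  d <- dim(kspace@data)
  if (pattern@nPE != d[2L])
    .stopf("pattern nPE (%d) does not match ky dimension (%d)",
           pattern@nPE, d[2L])
  dat <- kspace@data
  msk <- kspace@mask
  for (ti in seq_len(d[4L])) {
    m <- buildMask(pattern, ti)
    dat[, !m, , ti] <- 0+0i
    msk[!m, , ti] <- FALSE
    msk[m, , ti] <- msk[m, , ti] & kspace@mask[m, , ti]
  }
  new("KSpaceSeries", data = dat, mask = msk, voxelSize = kspace@voxelSize,
      frameTimes = kspace@frameTimes,
      acqParams = c(kspace@acqParams,
                    list(reduction = pattern@reduction,
                         nACS = pattern@nACS)))
}

#' Construct acquisition parameters
#'
#' Defaults are the accelerated whole-stomach protocol: TR 10.6 ms, TE
#' 1.6 ms, FA 25 deg, 24 slices of 1.5 mm in 6 packets of 4, FOV
#' 64 x 42 mm, matrix 128 x 84, and 24 phase-encode lines acquired per
#' slice per dynamic frame. The per-frame line count is deliberately an
#' independent parameter rather than derived from `nPE`/`nACS`/`R`, so
#' that protocol variants can be timed directly (see
#' [volumeAcquisitionTime]).
#'
#' @param tr,te repetition and echo time, ms.
#' @param fa flip angle, degrees.
#' @param nSlices,slicesPerPacket,nPackets slice grouping.
#' @param linesPerSlicePerFrame phase-encode lines acquired per slice per
#'   dynamic frame.
#' @param fov field of view, mm.
#' @param matrixSize acquisition matrix.
#' @param sliceThickness mm.
#' @return a validated [AcquisitionParams-class].
#' @export
acquisitionParams <- function(tr = 10.6, te = 1.6, fa = 25,
                              nSlices = 24L, slicesPerPacket = 4L,
                              nPackets = 6L, linesPerSlicePerFrame = 24L,
                              fov = c(64, 42), matrixSize = c(128L, 84L),
                              sliceThickness = 1.5) {
  new("AcquisitionParams", tr = tr, te = te, fa = fa,
      nSlices = as.integer(nSlices),
      slicesPerPacket = as.integer(slicesPerPacket),
      nPackets = as.integer(nPackets),
      linesPerSlicePerFrame = as.integer(linesPerSlicePerFrame),
      fov = fov, matrixSize = as.integer(matrixSize),
      sliceThickness = sliceThickness)
}

#' Acquisition time of one image volume
#'
#' All slices of a packet are excited within one TR period, so a volume
#' takes `nPackets * linesPerSlicePerFrame * TR`. With the default
#' protocol this is 6 x 24 x 10.6 ms = 1.526 s, the "roughly 1.5 s per
#' volume" of the accelerated scheme.
#'
#' @param params an [AcquisitionParams-class].
#' @return volume acquisition time, s.
#' @export
volumeAcquisitionTime <- function(params) {
  validObject(params)
  params@nPackets * params@linesPerSlicePerFrame * params@tr / 1000
}

#' Detect respiration triggers
#'
#' Places one trigger per detected inhalation burst, at the burst's
#' falling edge (the onset of the quiescent slow-exhalation phase in which
#' acquisition is allowed).
#'
#' @param trace a [RespirationTrace-class].
#' @param threshold pressure threshold; `NULL` uses the midrange
#'   `min + 0.5 * (max - min)`. A flat trace yields no triggers.
#' @return strictly increasing trigger times, s (possibly empty).
#' @export
detectTriggers <- function(trace, threshold = NULL) {
  stopifnot(is(trace, "RespirationTrace"))
  p <- trace@pressure
  if (!length(p)) .stopf("empty respiration trace")
  rng <- range(p)
  if (diff(rng) == 0) return(numeric())
  thr <- threshold %||% (rng[1L] + 0.5 * diff(rng))
  above <- p >= thr
  falling <- which(above[-length(above)] & !above[-1L]) + 1L
  trace@times[falling]
}

#' Schedule volume acquisitions from respiration triggers
#'
#' A volume starts at the first trigger at or after the previous volume's
#' end; triggers arriving during an ongoing volume are ignored (no
#' re-triggering). The effective temporal resolution of a volume is the
#' start-to-start interval to the next volume: with periodic triggers of
#' cycle `c` it equals `ceiling(volumeTime / c) * c`, hence at most 3 s
#' for cycles of 1-2 s and a 1.5 s volume.
#'
#' @param triggers increasing trigger times, s.
#' @param volumeTime duration of one volume acquisition, s.
#' @param nVolumes maximal number of volumes to schedule; if the triggers
#'   run out earlier the schedule is truncated with a warning.
#' @return an [AcquisitionSchedule-class].
#' @export
scheduleVolumes <- function(triggers, volumeTime, nVolumes = Inf) {
  if (length(triggers) > 1L && any(diff(triggers) <= 0))
    .stopf("triggers must be strictly increasing")
  if (volumeTime <= 0) .stopf("volumeTime must be > 0")
  starts <- numeric()
  i <- 1L
  while (i <= length(triggers) && length(starts) < nVolumes) {
    t0 <- triggers[i]
    if (!length(starts) || t0 >= starts[length(starts)] + volumeTime) {
      starts <- c(starts, t0)
    }
    i <- i + 1L
  }
  truncated <- is.finite(nVolumes) && length(starts) < nVolumes
  if (truncated)
    .warnf("only %d of %d volumes could be scheduled before triggers ran out",
           length(starts), nVolumes)
  res <- c(diff(starts), NA_real_)
  new("AcquisitionSchedule", triggerTimes = as.numeric(triggers),
      volumeStart = starts, volumeEnd = starts + volumeTime,
      effectiveResolution = res,
      truncated = isTRUE(truncated))
}
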