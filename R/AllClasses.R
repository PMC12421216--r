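#' @import methods
NULL

## Central containers for the dynamic gastric MRI toolkit. All physical
## coordinates are millimetres measured from the grid corner; axis order for
## image-domain arrays is (x, y, slice, time), for k-space (kx, ky, slice,
## time). Frame times are seconds.

#' TissueProperties: saturation-recovery signal model parameters
#'
#' Longitudinal relaxation times of the gadolinium-doped luminal content and
#' of the surrounding tissue, together with the effective recovery time
#' between the spatial saturation pulse and the echo at the centre of
#' k-space. The contrast premise of the method is `t1Lumen < t1Tissue`: the
#' doped meal recovers essentially fully within the recovery interval while
#' tissue recovers only marginally.
#'
#' @slot t1Lumen T1 of the doped luminal content, ms (default 17).
#' @slot t1Tissue T1 of surrounding tissue, ms (default 800).
#' @slot tRec effective recovery time between saturation and the k-space
#'   centre echo, ms (default 127).
#' @slot backgroundLevel intensity of the background (outside the body),
#'   dimensionless in `[0, 1)`.
#' @slot tissueBase relative base proton density of tissue w.r.t. the meal
#'   (free parameter of the model, default 1).
#' @export
setClass("TissueProperties",
  representation(t1Lumen = "numeric", t1Tissue = "numeric", tRec = "numeric",
                 backgroundLevel = "numeric", tissueBase = "numeric"),
  prototype(t1Lumen = 17, t1Tissue = 800, tRec = 127,
            backgroundLevel = 0.02, tissueBase = 1))

setValidity("TissueProperties", function(object) {
  msg <- character()
  if (object@t1Lumen <= 0 || object@t1Tissue <= 0 || object@tRec <= 0)
    msg <- c(msg, "all times must be > 0")
  if (object@t1Lumen >= object@t1Tissue)
    msg <- c(msg, "t1Lumen must be < t1Tissue (contrast premise)")
  if (object@backgroundLevel < 0 || object@backgroundLevel >= 1)
    msg <- c(msg, "backgroundLevel must lie in [0, 1)")
  if (object@tissueBase < 0)
    msg <- c(msg, "tissueBase must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomConfig: geometry and motion of the synthetic stomach
#'
#' Describes a piecewise-homogeneous luminal compartment (an antral tube
#' running in the slice direction joined to a corpus/fundus ellipsoid)
#' inside a cylindrical body of suppressed tissue, plus the contraction
#' wave, respiration, and noise parameters. Defaults are the study
#' conditions of the method: contraction amplitude 0.231 (occlusion ratio
#' on radius), frequency 5.3 cpm, propagation speed 0.56 mm/s, respiration
#' mid-range at 45 cpm.
#'
#' @slot grid voxel counts (nx, ny, nSlices).
#' @slot voxelSize voxel size (dx, dy, dz) in mm.
#' @slot antrumCenter in-plane centre (x, y) of the antral tube, mm.
#' @slot antrumRadius resting antral radius, mm.
#' @slot corpusCenter centre (x, y, z) of the corpus/fundus ellipsoid, mm.
#' @slot corpusSemiaxes ellipsoid semi-axes (a, b, c), mm.
#' @slot bodyCenter in-plane centre of the body cylinder, mm.
#' @slot bodyRadius radius of the body cylinder, mm.
#' @slot contractionAmplitude occlusion ratio applied to the radius, `[0,1)`.
#' @slot contractionFrequency contraction frequency, cycles per minute.
#' @slot contractionVelocity propagation speed of the wave, mm/s.
#' @slot contractionWavelength wavelength of the occlusion profile, mm;
#'   `NA` derives it as `velocity * 60 / frequency` so that frequency and
#'   velocity are simultaneously honoured.
#' @slot respirationRate respiration rate, cycles per minute.
#' @slot respirationDisplacement rigid through-plane displacement during
#'   inhalation bursts, mm (0 emulates perfect gating).
#' @slot noiseSigma additive Gaussian noise s.d. as a fraction of the lumen
#'   signal.
#' @slot seed integer seed for the noise generator.
#' @export
setClass("PhantomConfig",
  representation(grid = "integer", voxelSize = "numeric",
                 antrumCenter = "numeric", antrumRadius = "numeric",
                 corpusCenter = "numeric", corpusSemiaxes = "numeric",
                 bodyCenter = "numeric", bodyRadius = "numeric",
                 contractionAmplitude = "numeric",
                 contractionFrequency = "numeric",
                 contractionVelocity = "numeric",
                 contractionWavelength = "numeric",
                 respirationRate = "numeric",
                 respirationDisplacement = "numeric",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (length(object@grid) != 3L || any(object@grid[1:2] < 8L) ||
      object@grid[3L] < 1L)
    msg <- c(msg, "grid needs in-plane counts >= 8 and >= 1 slice")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxel sizes must be > 0")
  if (object@contractionAmplitude < 0 || object@contractionAmplitude >= 1)
    msg <- c(msg, "contractionAmplitude must lie in [0, 1)")
  if (object@contractionFrequency <= 0)
    msg <- c(msg, "contractionFrequency must be > 0")
  if (object@contractionVelocity <= 0)
    msg <- c(msg, "contractionVelocity must be > 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@antrumRadius <= 0) msg <- c(msg, "antrumRadius must be > 0")
  fov <- object@grid * object@voxelSize
  if (any(object@antrumCenter + object@antrumRadius > fov[1:2]) ||
      any(object@antrumCenter - object@antrumRadius < 0))
    msg <- c(msg, "grid too small to contain the antral tube")
  if (length(msg)) msg else TRUE
})

#' ImageSeries: real-valued dynamic image stack
#'
#' @slot values numeric 4D array on (x, y, slice, time).
#' @slot voxelSize (dx, dy, dz) in mm.
#' @slot frameTimes frame acquisition times in seconds, strictly increasing.
#' @slot provenance free-text label of how the series was produced.
#' @export
setClass("ImageSeries",
  representation(values = "array", voxelSize = "numeric",
                 frameTimes = "numeric", provenance = "character"))

setValidity("ImageSeries", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 4L)
    msg <- c(msg, "values must be a 4D (x, y, slice, time) array")
  else if (length(object@frameTimes) != dim(object@values)[4L])
    msg <- c(msg, "frameTimes length must equal the time dimension")
  if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths")
  if (length(msg)) msg else TRUE
})

#' KSpaceSeries: complex k-space samples with a line-sampling mask
#'
#' @slot data complex 4D array on (kx, ky, slice, time), DC at the centred
#'   position `floor(n/2) + 1` along each in-plane axis.
#' @slot mask logical array (ky, slice, time); `FALSE` lines are unsampled
#'   and hold zeros.
#' @slot voxelSize voxel size of the underlying image grid, mm.
#' @slot frameTimes frame times in seconds.
#' @slot acqParams named list of acquisition attributes (TR/TE/FA/FOV/...).
#' @export
setClass("KSpaceSeries",
  representation(data = "array", mask = "array", voxelSize = "numeric",
                 frameTimes = "numeric", acqParams = "list"))

setValidity("KSpaceSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, "data must be a 4D (kx, ky, slice, time) array")
  if (!is.complex(object@data)) msg <- c(msg, "data must be complex")
  md <- dim(object@mask)
  if (length(md) != 3L || (length(d) == 4L && !all(md == d[2:4])))
    msg <- c(msg, "mask must be (ky, slice, time) matching data")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(d) == 4L && length(object@frameTimes) != d[4L])
    msg <- c(msg, "frameTimes length must equal the time dimension")
  if (length(msg)) msg else TRUE
})

#' SamplingPattern: time-interleaved Cartesian undersampling
#'
#' Central `nACS` phase-encode lines are always sampled; peripheral lines
#' are sampled every `reduction`-th line with a phase offset that advances
#' by one per frame, so the union of `reduction` consecutive frames covers
#' every line.
#'
#' @slot nPE number of phase-encode lines.
#' @slot nACS number of fully sampled autocalibration lines, centred so the
#'   DC line is the upper-middle ACS line for even `nACS`.
#' @slot reduction integer reduction factor R >= 1 for the periphery.
#' @slot phaseOffsets optional integer vector of per-frame phase offsets in
#'   `0..R-1` (recycled); empty means the default rule, offset
#'   `(frame - 1) mod R`.
#' @export
setClass("SamplingPattern",
  representation(nPE = "integer", nACS = "integer", reduction = "integer",
                 phaseOffsets = "integer"))

setValidity("SamplingPattern", function(object) {
  msg <- character()
  if (object@nPE < 1L) msg <- c(msg, "nPE must be >= 1")
  if (object@nACS < 0L || object@nACS > object@nPE)
    msg <- c(msg, "nACS must lie in [0, nPE]")
  if (object@reduction < 1L) msg <- c(msg, "reduction must be >= 1")
  if (length(object@phaseOffsets) &&
      (any(object@phaseOffsets < 0L) ||
       any(object@phaseOffsets >= object@reduction)))
    msg <- c(msg, "phaseOffsets must lie in 0..R-1")
  if (length(msg)) msg else TRUE
})

#' RespirationTrace: simulated pressure-pillow respiration signal
#'
#' One short inhalation burst per cycle followed by a quiescent
#' slow-exhalation baseline.
#'
#' @slot times uniformly spaced sample times, s.
#' @slot pressure pressure in arbitrary units.
#' @slot rateNominal nominal respiration rate, cpm.
#' @export
setClass("RespirationTrace",
  representation(times = "numeric", pressure = "numeric",
                 rateNominal = "numeric"))

setValidity("RespirationTrace", function(object) {
  if (length(object@times) != length(object@pressure))
    return("times and pressure must have equal length")
  TRUE
})

#' AcquisitionParams: multi-slice gradient-echo protocol parameters
#'
#' @slot tr repetition time, ms.
#' @slot te echo time, ms.
#' @slot fa flip angle, degrees.
#' @slot nSlices total number of slices.
#' @slot slicesPerPacket adjacent slices excited within one TR period.
#' @slot nPackets number of slice packets; `nSlices = slicesPerPacket *
#'   nPackets`.
#' @slot linesPerSlicePerFrame phase-encode lines acquired per slice per
#'   dynamic frame.
#' @slot fov field of view (x, y), mm.
#' @slot matrixSize acquisition matrix (x, y).
#' @slot sliceThickness slice thickness, mm.
#' @export
setClass("AcquisitionParams",
  representation(tr = "numeric", te = "numeric", fa = "numeric",
                 nSlices = "integer", slicesPerPacket = "integer",
                 nPackets = "integer", linesPerSlicePerFrame = "integer",
                 fov = "numeric", matrixSize = "integer",
                 sliceThickness = "numeric"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@nSlices != object@slicesPerPacket * object@nPackets)
    msg <- c(msg, "nSlices must equal slicesPerPacket * nPackets")
  if (object@tr <= 0 || object@te < 0)
    msg <- c(msg, "tr must be > 0 and te >= 0")
  if (object@linesPerSlicePerFrame < 1L)
    msg <- c(msg, "linesPerSlicePerFrame must be >= 1")
  if (length(msg)) msg else TRUE
})

#' AcquisitionSchedule: respiration-gated volume timing
#'
#' @slot triggerTimes respiration trigger times used, s.
#' @slot volumeStart start time of each acquired volume, s.
#' @slot volumeEnd end time of each volume, s.
#' @slot effectiveResolution start-to-start interval per volume, s (last
#'   entry `NA`).
#' @slot truncated `TRUE` when the trigger list ran out before the
#'   requested number of volumes.
#' @export
setClass("AcquisitionSchedule",
  representation(triggerTimes = "numeric", volumeStart = "numeric",
                 volumeEnd = "numeric", effectiveResolution = "numeric",
                 truncated = "logical"))

setValidity("AcquisitionSchedule", function(object) {
  n <- length(object@volumeStart)
  if (length(object@volumeEnd) != n ||
      length(object@effectiveResolution) != n)
    return("volumeStart/volumeEnd/effectiveResolution lengths differ")
  if (n > 1L && any(object@volumeStart[-1] < object@volumeEnd[-n]))
    return("volumes must not overlap")
  TRUE
})

#' KTKernelSet: calibrated k-t interpolation kernels
#'
#' For each missing phase-encode phase `d` in `1..R-1` (and each clamped
#' temporal window near the sequence edges) holds the source stencil as
#' integer offsets `(dky, dt)` restricted to sampled lines, extended by
#' `+/- kxHalfWidth` frequency-encode taps, and the complex weights fitted
#' on the autocalibration region.
#'
#' @slot reduction reduction factor R.
#' @slot kxHalfWidth frequency-encode tap half-width (default 2, 5 taps).
#' @slot kyHalfWidth maximal `|dky|` of a source line (default 2).
#' @slot tWindow temporal window length in frames (default R).
#' @slot shapes named list, one entry per (phase, window variant):
#'   `list(d, dts, sources, weights)` with `sources` a 2-column matrix of
#'   `(dky, dt)` offsets.
#' @slot calibrated whether weights have been fitted.
#' @export
setClass("KTKernelSet",
  representation(reduction = "integer", kxHalfWidth = "integer",
                 kyHalfWidth = "integer", tWindow = "integer",
                 shapes = "list", calibrated = "logical"),
  prototype(calibrated = FALSE))

setValidity("KTKernelSet", function(object) {
  if (object@reduction < 2L) return("reduction must be >= 2")
  for (sh in object@shapes) {
    if (length(unique(sh$sources[, 2L])) < 2L)
      return("each kernel shape needs >= 2 temporal source frames")
    if (!is.null(sh$weights) && any(!is.finite(Mod(sh$weights))))
      return("kernel weights must be finite")
  }
  TRUE
})

#' AreaTimeSeries: luminal cross-sectional area over time
#'
#' @slot position arc-length position along the antral axis, mm.
#' @slot times frame times, s.
#' @slot areas cross-sectional areas, mm^2.
#' @slot peaks indices of relaxation peaks (after [detectExtrema]).
#' @slot valleys indices of contraction valleys.
#' @export
setClass("AreaTimeSeries",
  representation(position = "numeric", times = "numeric", areas = "numeric",
                 peaks = "integer", valleys = "integer"),
  prototype(peaks = integer(), valleys = integer()))

setValidity("AreaTimeSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@areas))
    return("times and areas must have equal length")
  if (any(object@areas < 0)) msg <- c(msg, "areas must be >= 0")
  idx <- sort(c(object@peaks, object@valleys))
  if (length(object@peaks) && length(object@valleys)) {
    typ <- ifelse(idx %in% object@peaks, "p", "v")
    if (any(typ[-1] == typ[-length(typ)]))
      msg <- c(msg, "peaks and valleys must alternate in time")
  }
  if (length(msg)) msg else TRUE
})

#' MotilityMetrics: antral contraction and volume summary
#'
#' @slot amplitude occlusion ratio on cross-sectional area, `[0, 1]`.
#' @slot amplitudeRadius radius-equivalent occlusion ratio,
#'   `1 - sqrt(1 - amplitude)`.
#' @slot frequency dominant contraction frequency, cpm.
#' @slot velocity propagation velocity, mm/s.
#' @slot volume time-averaged luminal volume, mL.
#' @slot perPosition data.frame of per-cross-section estimates.
#' @export
setClass("MotilityMetrics",
  representation(amplitude = "numeric", amplitudeRadius = "numeric",
                 frequency = "numeric", velocity = "numeric",
                 volume = "numeric", perPosition = "data.frame"))

setValidity("MotilityMetrics", function(object) {
  ok <- c(object@amplitude, object@frequency, object@volume)
  if (any(ok < 0, na.rm = TRUE)) return("metrics must be non-negative")
  if (!is.na(object@amplitude) && object@amplitude > 1)
    return("amplitude must be <= 1")
  TRUE
})

#' RunConfig: validated end-to-end pipeline configuration
#'
#' Bundles the phantom, tissue, sampling, reconstruction, and analysis
#' parameters of one simulation run; every stage's parameters are
#' validated on construction, before any stage executes.
#'
#' @slot phantom a [PhantomConfig-class].
#' @slot tissue a [TissueProperties-class].
#' @slot frameTimes frame times, s.
#' @slot reduction undersampling reduction factor R.
#' @slot nACS number of autocalibration lines.
#' @slot kxHalfWidth kernel frequency-encode tap half-width.
#' @slot kyHalfWidth kernel maximal `|dky|`.
#' @slot ssimWindow SSIM window side, pixels.
#' @slot positions cross-section positions along the antral axis, mm
#'   (empty = automatic).
#' @slot seed master seed.
#' @slot outDir output directory ("" = return results only).
#' @export
setClass("RunConfig",
  representation(phantom = "PhantomConfig", tissue = "TissueProperties",
                 frameTimes = "numeric", reduction = "integer",
                 nACS = "integer", kxHalfWidth = "integer",
                 kyHalfWidth = "integer", ssimWindow = "integer",
                 positions = "numeric", seed = "integer",
                 outDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@frameTimes) < 2L ||
      any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be >= 2 strictly increasing times")
  if (object@reduction < 1L) msg <- c(msg, "reduction must be >= 1")
  if (object@nACS < 2L || object@nACS > object@phantom@grid[2L])
    msg <- c(msg, "nACS must lie in [2, ny]")
  if (length(msg)) msg else TRUE
})
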