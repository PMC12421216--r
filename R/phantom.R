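#' @include AllClasses.R utils.R
NULL

#' Saturation-recovery fraction
#'
#' Fraction of longitudinal magnetization recovered a time `tRec` after a
#' saturation pulse, `1 - exp(-tRec / t1)`. This is the signal model behind
#' the luminal contrast: the gadolinium-doped meal (T1 ~ 17 ms) recovers
#' essentially fully within the ~127 ms effective recovery interval, while
#' surrounding tissue (T1 > 800 ms) recovers less than 20%.
#'
#' @param tRec recovery time, ms (>= 0).
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @return recovered fraction in `[0, 1)`; increasing in `tRec`,
#'   decreasing in `t1`.
#' @examples
#' saturationRecoveryFraction(127, 800)  # tissue, ~0.147
#' saturationRecoveryFraction(127, 17)   # doped meal, ~0.9994
#' @export
saturationRecoveryFraction <- function(tRec, t1) {
  if (any(t1 <= 0)) .stopf("t1 must be positive")
  if (any(tRec < 0)) .stopf("tRec must be non-negative")
  1 - exp(-tRec / t1)
}

#' Dilution concentration of the contrast meal
#'
#' Concentration after mixing a stock solution into a diluent, assuming
#' additive volumes: `stockConc * stockVol / (stockVol + diluentVol)`.
#'
#' @param stockConc stock concentration, mM (>= 0).
#' @param stockVol stock volume, mL (> 0).
#' @param diluentVol diluent volume, mL (>= 0).
#' @return diluted concentration, mM.
#' @examples
#' dilutionConcentration(182, 1, 25)  # the 7 mM doped test meal
#' @export
dilutionConcentration <- function(stockConc, stockVol, diluentVol) {
  if (any(stockConc < 0)) .stopf("concentration must be non-negative")
  if (any(stockVol <= 0) || any(diluentVol < 0) ||
      any(stockVol + diluentVol <= 0))
    .stopf("volumes must be positive")
  stockConc * stockVol / (stockVol + diluentVol)
}

#' Construct tissue properties
#'
#' @param t1Lumen,t1Tissue,tRec times in ms.
#' @param backgroundLevel,tissueBase dimensionless levels; see
#'   [TissueProperties-class].
#' @return a validated [TissueProperties-class].
#' @export
tissueProperties <- function(t1Lumen = 17, t1Tissue = 800, tRec = 127,
                             backgroundLevel = 0.02, tissueBase = 1) {
  new("TissueProperties", t1Lumen = t1Lumen, t1Tissue = t1Tissue,
      tRec = tRec, backgroundLevel = backgroundLevel,
      tissueBase = tissueBase)
}

#' Construct a phantom configuration
#'
#' Defaults describe the desk-scale study conditions: a 64 x 64 x 4 grid at
#' 0.5 x 0.5 x 1.5 mm, an antral tube of resting radius 3 mm running in the
#' slice direction, a corpus/fundus ellipsoid joined to its dorsal end, and
#' a contraction wave with occlusion ratio 0.231 (on radius), frequency
#' 5.3 cpm and propagation speed 0.56 mm/s.
#'
#' @param grid,voxelSize,antrumCenter,antrumRadius,corpusCenter,corpusSemiaxes
#'   geometry; see [PhantomConfig-class].
#' @param bodyCenter,bodyRadius body cylinder, mm.
#' @param contractionAmplitude,contractionFrequency,contractionVelocity,contractionWavelength
#'   contraction wave parameters; `contractionWavelength = NA` derives
#'   `velocity * 60 / frequency`.
#' @param respirationRate,respirationDisplacement respiration, cpm and mm.
#' @param noiseSigma,seed noise level (fraction of lumen signal) and seed.
#' @return a validated [PhantomConfig-class].
#' @export
phantomConfig <- function(grid = c(64L, 64L, 4L),
                          voxelSize = c(0.5, 0.5, 1.5),
                          antrumCenter = c(10.25, 16.25),
                          antrumRadius = 3,
                          corpusCenter = c(10.25, 16.25, 9),
                          corpusSemiaxes = c(8, 7, 5),
                          bodyCenter = c(16, 16),
                          bodyRadius = 14,
                          contractionAmplitude = 0.231,
                          contractionFrequency = 5.3,
                          contractionVelocity = 0.56,
                          contractionWavelength = NA_real_,
                          respirationRate = 45,
                          respirationDisplacement = 0,
                          noiseSigma = 0, seed = 1L) {
  num <- function(x) as.numeric(unlist(x))
  new("PhantomConfig", grid = as.integer(unlist(grid)),
      voxelSize = num(voxelSize),
      antrumCenter = num(antrumCenter), antrumRadius = num(antrumRadius),
      corpusCenter = num(corpusCenter), corpusSemiaxes = num(corpusSemiaxes),
      bodyCenter = num(bodyCenter), bodyRadius = num(bodyRadius),
      contractionAmplitude = num(contractionAmplitude),
      contractionFrequency = num(contractionFrequency),
      contractionVelocity = num(contractionVelocity),
      contractionWavelength = num(contractionWavelength),
      respirationRate = num(respirationRate),
      respirationDisplacement = num(respirationDisplacement),
      noiseSigma = num(noiseSigma), seed = as.integer(seed))
}

#' Default dynamic frame times
#'
#' Frames every 2 s, the effective temporal resolution obtained when a
#' 1.5 s volume acquisition is gated by a 1 s respiration cycle.
#'
#' @param n number of frames.
#' @param dt frame interval, s.
#' @return numeric vector of frame times starting at 0.
#' @export
defaultFrameTimes <- function(n = 60L, dt = 2) seq(0, by = dt, length.out = n)

## wavelength of the occlusion profile (mm)
.waveLambda <- function(config) {
  if (is.na(config@contractionWavelength))
    config@contractionVelocity * 60 / config@contractionFrequency
  else config@contractionWavelength
}

## unit-amplitude raised-cosine occlusion profile, periodic in u / lambda;
## 0 at the wave crest of the lumen (no occlusion), 1 at the trough
.occlusionProfile <- function(u, lambda) {
  0.5 * (1 - cos(2 * pi * (u / lambda)))
}

## rigid through-plane respiration shift (mm) at time t: sinusoidal during
## the inhalation burst (first burstFraction of each cycle), zero in the
## quiescent phase
.respShift <- function(config, t, burstFraction = 0.2) {
  if (config@respirationDisplacement == 0) return(rep(0, length(t)))
  cyc <- 60 / config@respirationRate
  ph <- (t %% cyc) / cyc
  ifelse(ph < burstFraction,
         config@respirationDisplacement * sin(pi * ph / burstFraction), 0)
}

## local antral radius (mm) at through-plane position z and time t
.antralRadius <- function(config, z, t) {
  lam <- .waveLambda(config)
  w <- .occlusionProfile(z - config@contractionVelocity * t, lam)
  config@antrumRadius * (1 - config@contractionAmplitude * w)
}

## continuous-geometry lumen membership at physical points (x, y, z) and
## time t; z already respiration-shifted by the caller
.inLumen <- function(config, x, y, z, t) {
  r <- .antralRadius(config, z, t)
  tube <- (x - config@antrumCenter[1L])^2 +
          (y - config@antrumCenter[2L])^2 <= r^2
  cs <- config@corpusCenter; ca <- config@corpusSemiaxes
  corpus <- ((x - cs[1L]) / ca[1L])^2 + ((y - cs[2L]) / ca[2L])^2 +
            ((z - cs[3L]) / ca[3L])^2 <= 1
  tube | corpus
}

## voxel-centre coordinate vectors (mm)
.gridCenters <- function(config) {
  g <- config@grid; vs <- config@voxelSize
  list(x = (seq_len(g[1L]) - 0.5) * vs[1L],
       y = (seq_len(g[2L]) - 0.5) * vs[2L],
       z = (seq_len(g[3L]) - 0.5) * vs[3L])
}

## fractional in-plane occupancy of the lumen per voxel: each voxel is
## subdivided supersample x supersample in-plane and the membership
## fraction of the subcells is returned. Boundary voxels of acquired
## band-limited MRI magnitudes carry partial-volume intensities; the
## phantom reproduces that instead of hard binary edges.
.lumenOccupancy <- function(config, frameTimes, supersample = 4L) {
  g <- config@grid; vs <- config@voxelSize
  ss <- as.integer(supersample)
  sub <- (seq_len(ss) - 0.5) / ss
  fx <- as.vector(outer(sub, seq_len(g[1L]) - 1L, `+`)) * vs[1L]
  fy <- as.vector(outer(sub, seq_len(g[2L]) - 1L, `+`)) * vs[2L]
  xg <- matrix(fx, length(fx), length(fy))
  yg <- matrix(fy, length(fx), length(fy), byrow = TRUE)
  zc <- (seq_len(g[3L]) - 0.5) * vs[3L]
  shift <- .respShift(config, frameTimes)
  occ <- array(0, c(g, length(frameTimes)))
  for (ti in seq_along(frameTimes)) {
    for (s in seq_len(g[3L])) {
      m <- .inLumen(config, xg, yg, zc[s] - shift[ti], frameTimes[ti])
      dim(m) <- c(ss, g[1L], ss, g[2L])
      occ[, , s, ti] <- apply(m, c(2L, 4L), mean)
    }
  }
  occ
}

#' Ground-truth lumen mask of the phantom
#'
#' Voxels whose luminal occupancy fraction is at least one half at each
#' frame time; the reference against which segmentation is evaluated.
#'
#' @param config a [PhantomConfig-class].
#' @param frameTimes frame times, s.
#' @param supersample in-plane subdivision used for the occupancy
#'   fraction (1 = voxel-centre membership).
#' @return logical 4D array (x, y, slice, time).
#' @export
lumenMask <- function(config, frameTimes = defaultFrameTimes(),
                      supersample = 4L) {
  validObject(config)
  .lumenOccupancy(config, frameTimes, supersample) >= 0.5
}

#' The true antral axis of the phantom
#'
#' @param config a [PhantomConfig-class].
#' @return matrix of 3D points (mm) along the tube centreline, from the
#'   ventral face (z = 0) to the dorsal face.
#' @export
antralAxisTruth <- function(config) {
  zmax <- config@grid[3L] * config@voxelSize[3L]
  z <- seq(0, zmax, by = config@voxelSize[3L] / 2)
  cbind(x = config@antrumCenter[1L], y = config@antrumCenter[2L], z = z)
}

#' Continuous lumen volume of the phantom
#'
#' Volume of the continuous lumen geometry (antral tube with its occlusion
#' wave, plus the in-grid part of the corpus ellipsoid) evaluated by fine
#' spatial quadrature, independent of the voxel grid and of segmentation.
#'
#' @param config a [PhantomConfig-class].
#' @param times times at which to evaluate, s.
#' @param step quadrature step, mm.
#' @return numeric vector of volumes in mL, one per time.
#' @export
lumenVolume <- function(config, times = 0, step = 0.25) {
  g <- config@grid; vs <- config@voxelSize
  ext <- g * vs
  x <- seq(step / 2, ext[1L], by = step)
  y <- seq(step / 2, ext[2L], by = step)
  z <- seq(step / 2, ext[3L], by = step)
  xg <- matrix(x, length(x), length(y))
  yg <- matrix(y, length(x), length(y), byrow = TRUE)
  shift <- .respShift(config, times)
  vapply(seq_along(times), function(ti) {
    n <- 0
    for (zi in z)
      n <- n + sum(.inLumen(config, xg, yg, zi - shift[ti], times[ti]))
    n * step^3 / 1000
  }, numeric(1L))
}

#' Generate the dynamic stomach phantom
#'
#' Builds a piecewise-homogeneous dynamic image series: luminal voxels at
#' the saturation-recovery fraction of the doped meal, the surrounding body
#' at the (much lower) tissue recovery fraction scaled by its base level,
#' and the background at `backgroundLevel`. The antral radius at
#' through-plane position `z` and time `t` is
#' `r0 * (1 - A * w(z - v t))` with `w` a periodic unit-amplitude
#' raised-cosine occlusion profile, so the radius occlusion equals `A` at
#' the wave trough. Optional additive Gaussian noise (magnitude taken) and
#' rigid through-plane respiration displacement.
#'
#' @param config a [PhantomConfig-class].
#' @param tissue a [TissueProperties-class].
#' @param frameTimes non-empty, strictly increasing frame times, s.
#' @param supersample in-plane subdivision for partial-volume boundary
#'   intensities (1 = hard binary edges).
#' @return an [ImageSeries-class].
#' @export
generatePhantom <- function(config, tissue = tissueProperties(),
                            frameTimes = defaultFrameTimes(),
                            supersample = 4L) {
  validObject(config); validObject(tissue)
  if (!length(frameTimes) || any(diff(frameTimes) <= 0))
    .stopf("frameTimes must be non-empty and strictly increasing")
  g <- config@grid
  cc <- .gridCenters(config)
  xg <- matrix(cc$x, g[1L], g[2L])
  yg <- matrix(cc$y, g[1L], g[2L], byrow = TRUE)
  body <- (xg - config@bodyCenter[1L])^2 +
          (yg - config@bodyCenter[2L])^2 <= config@bodyRadius^2

  sigLumen <- saturationRecoveryFraction(tissue@tRec, tissue@t1Lumen)
  sigTissue <- tissue@tissueBase *
    saturationRecoveryFraction(tissue@tRec, tissue@t1Tissue)

  vals <- array(tissue@backgroundLevel, c(g, length(frameTimes)))
  occ <- .lumenOccupancy(config, frameTimes, supersample)
  for (ti in seq_along(frameTimes)) {
    for (s in seq_len(g[3L])) {
      plane <- matrix(tissue@backgroundLevel, g[1L], g[2L])
      plane[body] <- sigTissue
      ## partial-volume mixing at the luminal boundary
      plane <- plane * (1 - occ[, , s, ti]) + sigLumen * occ[, , s, ti]
      vals[, , s, ti] <- plane
    }
  }
  if (config@noiseSigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(config@seed)
    vals <- abs(vals + stats::rnorm(length(vals),
                                    sd = config@noiseSigma * sigLumen))
  }
  new("ImageSeries", values = vals, voxelSize = config@voxelSize,
      frameTimes = as.numeric(frameTimes), provenance = "phantom")
}

#' Simulate a respiration pressure trace
#'
#' One short inhalation pressure burst per cycle (a half-sine over the
#' first `burstFraction` of the cycle) followed by a quiescent
#' slow-exhalation baseline, emulating the pressure-pillow signal used for
#' gating. Optional per-cycle timing jitter.
#'
#' @param rate respiration rate, cpm (physiologic range ~30-60).
#' @param duration trace duration, s.
#' @param samplingRate sampling rate, Hz; must resolve at least 4 samples
#'   per cycle.
#' @param burstFraction burst duration as a fraction of the cycle.
#' @param jitter s.d. of cycle-start jitter as a fraction of the cycle.
#' @param seed seed used when `jitter > 0`.
#' @return a [RespirationTrace-class].
#' @export
simulateRespiration <- function(rate, duration, samplingRate = 100,
                                burstFraction = 0.2, jitter = 0,
                                seed = 1L) {
  if (rate <= 0 || duration <= 0) .stopf("rate and duration must be > 0")
  cyc <- 60 / rate
  if (samplingRate * cyc < 4)
    .stopf("sampling rate too low: < 4 samples per %.3g s cycle", cyc)
  times <- seq(0, duration, by = 1 / samplingRate)
  times <- times[times < duration]
  starts <- seq(0, duration + cyc, by = cyc)
  if (jitter > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    starts <- starts + c(0, stats::rnorm(length(starts) - 1L,
                                         sd = jitter * cyc))
  }
  pressure <- numeric(length(times))
  bdur <- burstFraction * cyc
  for (s0 in starts) {
    inb <- times >= s0 & times < s0 + bdur
    pressure[inb] <- pmax(pressure[inb], sin(pi * (times[inb] - s0) / bdur))
  }
  new("RespirationTrace", times = times, pressure = pressure,
      rateNominal = rate)
}

#' Forward Fourier model: image series to fully sampled k-space
#'
#' Per slice and frame, the centred 2D discrete Fourier transform of the
#' image plane (unnormalized forward DFT, DC at the grid centre). The
#' returned series is fully sampled (mask all `TRUE`). Under this
#' convention image energy equals k-space energy divided by `nx * ny`.
#'
#' @param images an [ImageSeries-class].
#' @return a [KSpaceSeries-class].
#' @export
phantomToKspace <- function(images) {
  stopifnot(is(images, "ImageSeries"))
  v <- images@values
  d <- dim(v)
  k <- array(complex(real = 0), d)
  for (ti in seq_len(d[4L]))
    for (s in seq_len(d[3L]))
      k[, , s, ti] <- .fft2c(v[, , s, ti])
  new("KSpaceSeries", data = k,
      mask = array(TRUE, d[2:4]), voxelSize = images@voxelSize,
      frameTimes = images@frameTimes, acqParams = list())
}
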