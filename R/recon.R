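#' @include AllClasses.R AllGenerics.R utils.R
NULL

## --- kernel geometry -------------------------------------------------------
##
## Time-interleaved lattice (default phase rule): at frame t the sampled
## peripheral lines satisfy ky0 = (t - 1) (mod R) (0-based ky0). A missing
## line at (ky0, t) has phase d = (ky0 - (t - 1)) mod R in 1..R-1. Relative
## to that target, the sampled lines of window frame offset dt sit at
## dky = m or m - R with m = (dt - d) mod R (m == 0 means the target line
## itself is sampled at that frame). Keeping |dky| <= kyHalfWidth yields a
## compact stencil that is translation-invariant in (kx, ky, t) and whose
## ky span fits inside the autocalibration block for every reduction factor
## of interest.

## temporal window of frame t: tWindow frames, centred, clamped inside 1..T
.windowOffsets <- function(tWindow, t, nT) {
  if (nT < tWindow)
    .stopf("frame count (%d) is smaller than the temporal window (%d)",
           nT, tWindow)
  hw <- (tWindow - 1L) %/% 2L
  ws <- min(max(t - hw, 1L), nT - tWindow + 1L)
  seq.int(ws, length.out = tWindow) - t
}

## source offsets (dky, dt) for phase d and window offsets dts
.kernelSources <- function(R, d, dts, kyMax) {
  src <- NULL
  for (dt in dts) {
    m <- (dt - d) %% R
    if (m == 0L) {
      src <- rbind(src, c(0L, dt))
    } else {
      if (m <= kyMax) src <- rbind(src, c(m, dt))
      if (R - m <= kyMax) src <- rbind(src, c(m - R, dt))
    }
  }
  if (is.null(src)) src <- matrix(integer(), 0L, 2L)
  colnames(src) <- c("dky", "dt")
  src[order(src[, 2L], src[, 1L]), , drop = FALSE]
}

.shapeKey <- function(d, dts) sprintf("d%d.w%d", d, dts[1L])

.makeShape <- function(R, d, dts, kyMax) {
  src <- .kernelSources(R, d, dts, kyMax)
  if (length(unique(src[, 2L])) < 2L)
    .stopf(paste("kernel windows too small: phase %d has sources in fewer",
                 "than 2 temporal frames"), d)
  list(d = d, dts = dts, sources = src, weights = NULL)
}

#' Enumerate the k-t kernel geometry
#'
#' Builds the uncalibrated kernel set for a reduction factor R: one kernel
#' shape per missing phase-encode phase `d = 1..R-1` (so two shapes for
#' R = 3), each collecting the sampled `(ky, t)` lattice neighbours within
#' a temporal window of `tWindow` frames centred on the target and within
#' `kyHalfWidth` lines of it, extended by `2 * kxHalfWidth + 1`
#' frequency-encode taps. Additional clamped-window variants near the
#' first/last frames are generated during calibration.
#'
#' @param reduction reduction factor R >= 2.
#' @param kxHalfWidth frequency-encode tap half-width (default 2: 5 taps).
#' @param kyHalfWidth maximal `|dky|` of a source line (default 2).
#' @param tWindow temporal window length in frames (default R).
#' @return an uncalibrated [KTKernelSet-class].
#' @export
ktKernelGeometry <- function(reduction, kxHalfWidth = 2L, kyHalfWidth = 2L,
                             tWindow = reduction) {
  reduction <- as.integer(reduction)
  if (reduction < 2L) .stopf("reduction must be >= 2")
  tWindow <- as.integer(tWindow)
  hw <- (tWindow - 1L) %/% 2L
  dts <- seq.int(-hw, length.out = tWindow)
  shapes <- list()
  for (d in seq_len(reduction - 1L))
    shapes[[.shapeKey(d, dts)]] <-
      .makeShape(reduction, d, dts, as.integer(kyHalfWidth))
  new("KTKernelSet", reduction = reduction,
      kxHalfWidth = as.integer(kxHalfWidth),
      kyHalfWidth = as.integer(kyHalfWidth),
      tWindow = tWindow, shapes = shapes, calibrated = FALSE)
}

## --- calibration -----------------------------------------------------------

## rows that are sampled in every (slice, frame): the autocalibration block
.alwaysSampledRows <- function(mask) {
  which(apply(mask, 1L, all))
}

## least squares via SVD; minimum-norm solution when rank deficient
.lstsq <- function(A, b) {
  sv <- La.svd(A)
  tol <- max(sv$d) * 1e-10
  r <- sum(sv$d > tol)
  if (r == 0L) .stopf("calibration system has numerical rank 0")
  ub <- (Conj(t(sv$u[, seq_len(r), drop = FALSE])) %*% b) / sv$d[seq_len(r)]
  w <- Conj(t(sv$vt[seq_len(r), , drop = FALSE])) %*% ub
  list(w = drop(w), rank = r, cond = sv$d[1L] / sv$d[length(sv$d)],
       rankDeficient = r < ncol(A))
}

## assemble and solve the ACS fit for one kernel shape
.calibrateShape <- function(dat, shape, kxHalfWidth, acsRows, frames,
                            slices, maxEquations) {
  d4 <- dim(dat)
  nx <- d4[1L]
  src <- shape$sources
  lo <- min(acsRows); hi <- max(acsRows)
  kyT <- acsRows[acsRows + min(src[, 1L]) >= lo &
                 acsRows + max(src[, 1L]) <= hi]
  ## kx is fully sampled and DFT-periodic, so every column contributes
  ## equations with circular tap indexing
  kxT <- seq_len(nx)
  grid <- expand.grid(kx = kxT, ky = kyT, s = slices, t = frames)
  n <- nrow(grid)
  nCoef <- nrow(src) * (2L * kxHalfWidth + 1L)
  if (n < nCoef)
    .stopf(paste("underdetermined calibration for kernel %s:",
                 "%d equations for %d weights"),
           .shapeKey(shape$d, shape$dts), n, nCoef)
  if (n > maxEquations) {
    keep <- unique(round(seq(1L, n, length.out = maxEquations)))
    grid <- grid[keep, , drop = FALSE]
    n <- nrow(grid)
  }
  b <- dat[cbind(grid$kx, grid$ky, grid$s, grid$t)]
  A <- matrix(0+0i, n, nCoef)
  j <- 0L
  for (i in seq_len(nrow(src))) {
    for (dkx in seq.int(-kxHalfWidth, kxHalfWidth)) {
      j <- j + 1L
      kxIdx <- ((grid$kx + dkx - 1L) %% nx) + 1L
      A[, j] <- dat[cbind(kxIdx, grid$ky + src[i, 1L],
                          grid$s, grid$t + src[i, 2L])]
    }
  }
  fit <- .lstsq(A, b)
  nb <- sqrt(sum(Mod(b)^2))
  resid <- if (nb > 0) sqrt(sum(Mod(A %*% fit$w - b)^2)) / nb else 0
  list(w = fit$w, nEq = n, resid = resid, cond = fit$cond,
       rankDeficient = fit$rankDeficient)
}

#' Calibrate k-t interpolation kernels on the autocalibration region
#'
#' For every kernel shape (each missing phase, including the dedicated
#' clamped-window variants at the temporal edges of the series) assembles
#' the unregularized linear least-squares problem from all autocalibration
#' positions -- across frequency-encode positions, frames and, by default,
#' slices -- where the full source stencil lies inside the autocalibration
#' block, and solves it by SVD. No regularizers are used; a rank-deficient
#' system yields the minimum-norm solution with a warning recorded in the
#' report.
#'
#' @param kspace a [KSpaceSeries-class]; its autocalibration lines must be
#'   sampled in every frame.
#' @param geometry an (uncalibrated) [KTKernelSet-class] from
#'   [ktKernelGeometry].
#' @param perSlice calibrate an independent weight set per slice instead
#'   of sharing one across slices.
#' @param maxEquations deterministic cap on the number of fit equations
#'   per kernel (evenly thinned when exceeded).
#' @return a list with elements `kernels` (calibrated
#'   [KTKernelSet-class]) and `report` (a data.frame with one row per
#'   kernel: equations, relative fit residual, condition number, rank
#'   deficiency).
#' @export
calibrateKernels <- function(kspace, geometry, perSlice = FALSE,
                             maxEquations = 2e5) {
  stopifnot(is(kspace, "KSpaceSeries"), is(geometry, "KTKernelSet"))
  dat <- kspace@data
  d4 <- dim(dat)
  nT <- d4[4L]
  W <- geometry@tWindow
  acsRows <- .alwaysSampledRows(kspace@mask)
  if (length(acsRows) < 2L ||
      !all(diff(acsRows) == 1L))
    .stopf("no contiguous autocalibration block present in every frame")
  R <- geometry@reduction
  kyMax <- geometry@kyHalfWidth
  khw <- geometry@kxHalfWidth

  ## group frames by their (clamped) window offsets
  winKey <- character(nT)
  winOff <- vector("list", nT)
  for (t in seq_len(nT)) {
    winOff[[t]] <- .windowOffsets(W, t, nT)
    winKey[t] <- winOff[[t]][1L]
  }
  shapes <- list()
  rows <- list()
  sliceSets <- if (perSlice) as.list(seq_len(d4[3L])) else
    list(seq_len(d4[3L]))
  for (key in unique(winKey)) {
    dts <- winOff[[which(winKey == key)[1L]]]
    ## shift invariance in time: any frame whose shifted stencil stays in
    ## range contributes fit equations, not only the frames at which this
    ## (possibly edge-clamped) window variant is applied
    frames <- which(seq_len(nT) + dts[1L] >= 1L &
                      seq_len(nT) + dts[length(dts)] <= nT)
    for (d in seq_len(R - 1L)) {
      sh <- .makeShape(R, d, dts, kyMax)
      wmat <- NULL
      for (sl in sliceSets) {
        res <- .calibrateShape(dat, sh, khw, acsRows, frames, sl,
                               maxEquations)
        if (res$rankDeficient)
          .warnf("kernel %s: rank-deficient fit, minimum-norm solution used",
                 .shapeKey(d, dts))
        wmat <- cbind(wmat, res$w)
        rows[[length(rows) + 1L]] <- data.frame(
          kernel = .shapeKey(d, dts), phase = d, windowStart = dts[1L],
          slice = if (perSlice) sl[1L] else NA_integer_,
          nEquations = res$nEq, nWeights = length(res$w),
          residual = res$resid, condition = res$cond,
          rankDeficient = res$rankDeficient)
      }
      sh$weights <- wmat
      shapes[[.shapeKey(d, dts)]] <- sh
    }
  }
  kernels <- new("KTKernelSet", reduction = R, kxHalfWidth = khw,
                 kyHalfWidth = kyMax, tWindow = W, shapes = shapes,
                 calibrated = TRUE)
  list(kernels = kernels, report = do.call(rbind, rows))
}

## --- interpolation ---------------------------------------------------------

#' Fill skipped phase-encode lines with calibrated kernels
#'
#' Every unsampled line is estimated by the kernel matching its phase and
#' temporal window; originally sampled lines (autocalibration and
#' peripheral) are kept bit-exactly, and only acquired lines ever act as
#' sources. Source positions falling outside the ky range are treated as
#' zero. A fully sampled input is returned unchanged.
#'
#' @param undersampled a [KSpaceSeries-class] produced with the default
#'   interleaving rule of the kernels' reduction factor.
#' @param kernels a calibrated [KTKernelSet-class].
#' @return a [KSpaceSeries-class] with all lines present.
#' @export
interpolateKspace <- function(undersampled, kernels) {
  stopifnot(is(undersampled, "KSpaceSeries"))
  if (all(undersampled@mask)) return(undersampled)
  stopifnot(is(kernels, "KTKernelSet"))
  if (!kernels@calibrated) .stopf("kernels are not calibrated")
  dat <- undersampled@data
  msk <- undersampled@mask
  d4 <- dim(dat)
  nx <- d4[1L]; nPE <- d4[2L]; nS <- d4[3L]; nT <- d4[4L]
  R <- kernels@reduction
  khw <- kernels@kxHalfWidth
  out <- dat
  for (t in seq_len(nT)) {
    offs <- (t - 1L) %% R
    dts <- .windowOffsets(kernels@tWindow, t, nT)
    lineMask <- apply(msk[, , t, drop = FALSE], 1L, all)
    missing <- which(!lineMask)
    for (ky in missing) {
      d <- ((ky - 1L) - offs) %% R
      if (d == 0L)
        .stopf("mask inconsistent with the kernels' phase rule at frame %d",
               t)
      key <- .shapeKey(d, dts)
      sh <- kernels@shapes[[key]]
      if (is.null(sh))
        .stopf("no calibrated kernel for phase %d, window start %d",
               d, dts[1L])
      wmat <- sh$weights
      acc <- matrix(0+0i, nx, nS)
      j <- 0L
      for (i in seq_len(nrow(sh$sources))) {
        ## k-space of a sampled image is periodic: index circularly
        kySrc <- ((ky + sh$sources[i, 1L] - 1L) %% nPE) + 1L
        tSrc <- t + sh$sources[i, 2L]
        plane <- dat[, kySrc, , tSrc, drop = TRUE]
        if (is.null(dim(plane))) plane <- matrix(plane, nx, nS)
        for (dkx in seq.int(-khw, khw)) {
          j <- j + 1L
          idx <- ((seq_len(nx) + dkx - 1L) %% nx) + 1L
          shifted <- plane[idx, , drop = FALSE]
          if (ncol(wmat) == 1L) {
            acc <- acc + wmat[j, 1L] * shifted
          } else {
            acc <- acc + shifted * matrix(wmat[j, ], nx, nS, byrow = TRUE)
          }
        }
      }
      out[, ky, , t] <- acc
    }
  }
  new("KSpaceSeries", data = out, mask = array(TRUE, d4[2:4]),
      voxelSize = undersampled@voxelSize,
      frameTimes = undersampled@frameTimes,
      acqParams = c(undersampled@acqParams, list(interpolated = TRUE)))
}

#' Reconstruct magnitude images from k-space
#'
#' Per slice and frame, the centred inverse 2D DFT with magnitude taken;
#' voxel size and frame times are carried over from the k-space metadata.
#'
#' @param kspace a [KSpaceSeries-class] with all lines present (sampled or
#'   interpolated).
#' @return an [ImageSeries-class].
#' @export
reconstructImages <- function(kspace) {
  stopifnot(is(kspace, "KSpaceSeries"))
  dat <- kspace@data
  d4 <- dim(dat)
  vals <- array(0, d4)
  for (t in seq_len(d4[4L]))
    for (s in seq_len(d4[3L]))
      vals[, , s, t] <- Mod(.ifft2c(dat[, , s, t]))
  new("ImageSeries", values = vals, voxelSize = kspace@voxelSize,
      frameTimes = kspace@frameTimes, provenance = "recon")
}
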