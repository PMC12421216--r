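#' @include AllClasses.R AllGenerics.R utils.R
NULL

## --- segmentation ----------------------------------------------------------

## largest 26/6-connected 3D component of one binary volume. Per-slice 2D
## labels from EBImage are merged across adjacent slices wherever the same
## in-plane voxel is foreground in both.
.largestComponent3d <- function(vol) {
  d <- dim(vol)
  labs <- array(0L, d)
  offset <- 0L
  nlab <- integer(d[3L])
  for (s in seq_len(d[3L])) {
    l <- EBImage::bwlabel(EBImage::Image(vol[, , s] * 1))
    l <- as.integer(l)
    nlab[s] <- max(l, 0L)
    l[l > 0L] <- l[l > 0L] + offset
    labs[, , s] <- l
    offset <- offset + nlab[s]
  }
  if (offset == 0L) return(array(FALSE, d))
  edges <- NULL
  if (d[3L] > 1L) {
    for (s in seq_len(d[3L] - 1L)) {
      a <- labs[, , s]; b <- labs[, , s + 1L]
      ov <- a > 0L & b > 0L
      if (any(ov)) edges <- rbind(edges, unique(cbind(a[ov], b[ov])))
    }
  }
  g <- igraph::make_empty_graph(n = offset, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp[labs[labs > 0L]], nbins = max(comp))
  keep <- which.max(sizes)
  out <- array(FALSE, d)
  out[labs > 0L] <- comp[labs[labs > 0L]] == keep
  out
}

#' Segment the luminal compartment
#'
#' Thresholds the magnitude images (Otsu's method on the pooled series
#' histogram by default -- the bright doped lumen against the suppressed
#' dark surroundings) and keeps the largest 3D connected component per
#' frame.
#'
#' @param images an [ImageSeries-class] (raw or normalized magnitudes).
#' @param threshold intensity threshold; `NULL` selects it by Otsu's
#'   method on the whole series.
#' @return logical 4D mask array with attribute `"threshold"`.
#' @export
segmentLumen <- function(images, threshold = NULL) {
  v <- .asValues(images)
  if (is.null(threshold)) {
    rng <- range(v)
    if (diff(rng) == 0) .stopf("empty segmentation: constant image series")
    vn <- (v - rng[1L]) / diff(rng)
    side <- ceiling(sqrt(length(vn)))
    pad <- c(vn, rep(vn[1L], side * side - length(vn)))
    th01 <- EBImage::otsu(EBImage::Image(matrix(pad, side, side)),
                          range = c(0, 1))
    threshold <- rng[1L] + th01 * diff(rng)
  }
  fg <- v > threshold
  if (!any(fg)) .stopf("empty segmentation: no voxel above threshold")
  d <- dim(v)
  out <- array(FALSE, d)
  for (t in seq_len(d[4L]))
    out[, , , t] <- .largestComponent3d(array(fg[, , , t], d[1:3]))
  if (!any(out)) .stopf("empty segmentation after component filtering")
  attr(out, "threshold") <- threshold
  out
}

## --- antral axis -----------------------------------------------------------

## 2D connected component of plane containing (or nearest to) point (ix, iy)
.planeComponentAt <- function(plane, ix, iy) {
  l <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(plane * 1))),
              nrow(plane), ncol(plane))
  lab <- 0L
  for (r in 0:1) {                     # direct hit, then 8-neighbourhood
    xi <- pmax(1L, ix - r):pmin(nrow(plane), ix + r)
    yi <- pmax(1L, iy - r):pmin(ncol(plane), iy + r)
    cand <- l[xi, yi, drop = FALSE]
    cand <- cand[cand > 0L]
    if (length(cand)) { lab <- cand[which.max(tabulate(cand))]; break }
  }
  if (lab == 0L) return(NULL)
  l == lab
}

#' Identify the longitudinal antral axis
#'
#' Returns the ordered centroid polyline of the antral lumen. With two
#' hint endpoints (mm) the axis is the centroid path between them: in each
#' slice crossed by the hint segment, the centroid of the in-plane
#' connected component containing the interpolated hint position; the
#' hint endpoints themselves cap the polyline. Without hints, the centroid
#' of the largest in-plane component of every slice is used. The result
#' carries the arc-length parameterization as attribute `"arclength"`.
#'
#' @param mask logical 3D or 4D lumen mask (a 4D mask is reduced to its
#'   time-majority volume: the axis is treated as stationary).
#' @param voxelSize (dx, dy, dz) in mm.
#' @param hints optional 2 x 3 matrix of endpoint coordinates, mm.
#' @return matrix of 3D points (mm), one row per slice crossed.
#' @export
antralAxis <- function(mask, voxelSize, hints = NULL) {
  if (length(dim(mask)) == 4L)
    mask <- apply(mask, 1:3, mean) > 0.5
  d <- dim(mask)
  if (!any(mask)) .stopf("mask is empty in the antral region")
  vs <- voxelSize
  centroids <- NULL
  if (!is.null(hints)) {
    hints <- as.matrix(hints)
    if (nrow(hints) != 2L || ncol(hints) != 3L)
      .stopf("hints must be a 2 x 3 matrix of endpoints (mm)")
    if (all(hints[1L, ] == hints[2L, ]))
      .stopf("hint endpoints must differ")
    zc <- (seq_len(d[3L]) - 0.5) * vs[3L]
    zr <- range(hints[, 3L])
    sl <- which(zc >= zr[1L] & zc <= zr[2L])
    if (!length(sl)) .stopf("hint segment crosses no slice")
    for (s in sl) {
      f <- if (diff(hints[, 3L]) == 0) 0.5 else
        (zc[s] - hints[1L, 3L]) / diff(hints[, 3L])
      pt <- hints[1L, ] + f * (hints[2L, ] - hints[1L, ])
      ix <- max(1L, min(d[1L], ceiling(pt[1L] / vs[1L])))
      iy <- max(1L, min(d[2L], ceiling(pt[2L] / vs[2L])))
      comp <- .planeComponentAt(mask[, , s], ix, iy)
      if (is.null(comp))
        .stopf("antral mask disconnected: no lumen at slice %d near the axis",
               s)
      idx <- which(comp, arr.ind = TRUE)
      centroids <- rbind(centroids,
                         c((mean(idx[, 1L]) - 0.5) * vs[1L],
                           (mean(idx[, 2L]) - 0.5) * vs[2L], zc[s]))
    }
    axis <- rbind(hints[1L, ], centroids, hints[2L, ])
    ord <- order(axis[, 3L] * sign(diff(hints[, 3L]))[1L])
    axis <- axis[ord, , drop = FALSE]
  } else {
    for (s in seq_len(d[3L])) {
      plane <- mask[, , s]
      if (!any(plane)) next
      l <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(plane * 1))),
                  d[1L], d[2L])
      lab <- which.max(tabulate(l[l > 0L]))
      idx <- which(l == lab, arr.ind = TRUE)
      centroids <- rbind(centroids,
                         c((mean(idx[, 1L]) - 0.5) * vs[1L],
                           (mean(idx[, 2L]) - 0.5) * vs[2L],
                           (s - 0.5) * vs[3L]))
    }
    if (is.null(centroids) || nrow(centroids) < 2L)
      .stopf("antral mask disconnected: fewer than 2 slices with lumen")
    axis <- centroids
  }
  seg <- sqrt(rowSums(diff(axis)^2))
  attr(axis, "arclength") <- c(0, cumsum(seg))
  colnames(axis) <- c("x", "y", "z")
  axis
}

## axis point and unit tangent at arc-length position s
.axisAt <- function(axis, s) {
  arc <- attr(axis, "arclength")
  if (s < arc[1L] - 1e-9 || s > arc[length(arc)] + 1e-9)
    .stopf("position %.3g mm outside the axis arc length [0, %.3g]",
           s, arc[length(arc)])
  i <- max(1L, findInterval(s, arc, rightmost.closed = TRUE))
  i <- min(i, nrow(axis) - 1L)
  f <- (s - arc[i]) / max(arc[i + 1L] - arc[i], 1e-12)
  p <- axis[i, ] + f * (axis[i + 1L, ] - axis[i, ])
  tg <- axis[i + 1L, ] - axis[i, ]
  list(point = p, tangent = tg / sqrt(sum(tg^2)))
}

## --- cross-sectional areas -------------------------------------------------

#' Luminal cross-sectional areas along the antral axis
#'
#' For each requested arc-length position, counts the lumen voxels whose
#' projection onto the local axis tangent lies within a slab of
#' `thickness` centred on the axis point, and converts the count to an
#' area (`count * voxelVolume / thickness`). When the tangent is close to
#' the slice normal only the in-plane connected component containing the
#' axis point is counted, so neighbouring luminal compartments crossing
#' the same slab do not contaminate the antral area.
#'
#' @param mask logical 4D lumen mask.
#' @param axis polyline from [antralAxis] (with `"arclength"` attribute).
#' @param positions arc-length positions along the axis, mm.
#' @param voxelSize (dx, dy, dz), mm.
#' @param frameTimes frame times, s.
#' @param thickness slab thickness, mm; defaults to the slice spacing.
#' @return list of [AreaTimeSeries-class], one per position.
#' @export
crossSectionAreas <- function(mask, axis, positions, voxelSize, frameTimes,
                              thickness = NULL) {
  d <- dim(mask)
  if (length(d) != 4L) .stopf("mask must be a 4D (x, y, slice, time) array")
  vs <- voxelSize
  thickness <- thickness %||% vs[3L]
  voxVol <- prod(vs)
  lapply(positions, function(pos) {
    loc <- .axisAt(axis, pos)
    areasV <- numeric(d[4L])
    if (abs(loc$tangent[3L]) > 0.9) {
      s0 <- max(1L, min(d[3L], ceiling(loc$point[3L] / vs[3L])))
      ix <- max(1L, min(d[1L], ceiling(loc$point[1L] / vs[1L])))
      iy <- max(1L, min(d[2L], ceiling(loc$point[2L] / vs[2L])))
      for (t in seq_len(d[4L])) {
        plane <- mask[, , s0, t]
        if (!any(plane)) { areasV[t] <- 0; next }
        comp <- .planeComponentAt(plane, ix, iy)
        areasV[t] <- if (is.null(comp)) 0 else
          sum(comp) * voxVol / thickness
      }
    } else {
      cx <- (seq_len(d[1L]) - 0.5) * vs[1L]
      cy <- (seq_len(d[2L]) - 0.5) * vs[2L]
      cz <- (seq_len(d[3L]) - 0.5) * vs[3L]
      proj <- outer(outer((cx - loc$point[1L]) * loc$tangent[1L],
                          (cy - loc$point[2L]) * loc$tangent[2L], `+`),
                    (cz - loc$point[3L]) * loc$tangent[3L], `+`)
      slab <- abs(proj) <= thickness / 2
      for (t in seq_len(d[4L]))
        areasV[t] <- sum(mask[, , , t] & slab) * voxVol / thickness
    }
    new("AreaTimeSeries", position = pos, times = as.numeric(frameTimes),
        areas = areasV)
  })
}

## --- extrema ---------------------------------------------------------------

#' Detect relaxation peaks and contraction valleys
#'
#' Local maxima (relaxation) and minima (contraction) of the area-time
#' series whose excursion exceeds `prominence` times the series range;
#' alternation is enforced by discarding the weaker of adjacent same-type
#' extrema, and adjacent peak/valley pairs of sub-threshold amplitude are
#' removed.
#'
#' @param series an [AreaTimeSeries-class] covering at least two
#'   contraction cycles.
#' @param prominence minimal excursion as a fraction of the series range.
#' @return the series with `peaks` and `valleys` indices filled.
#' @export
detectExtrema <- function(series, prominence = 0.1) {
  a <- series@areas
  n <- length(a)
  rng <- diff(range(a))
  ## collapse plateaus (quantized areas produce flat runs) before looking
  ## for sign changes; an extremum sits at the middle of its run
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dv <- diff(r$values)
  candRun <- which(dv[-length(dv)] * dv[-1L] < 0) + 1L
  cand <- (starts[candRun] + ends[candRun]) %/% 2L
  type <- ifelse(dv[candRun - 1L] > 0, "p", "v")
  if (!length(cand) || rng == 0)
    .stopf("no extrema found; record a longer series")
  ## enforce alternation: keep the stronger of adjacent same-type extrema
  keep <- rep(TRUE, length(cand))
  repeat {
    idx <- which(keep)
    tt <- type[idx]
    same <- which(tt[-1L] == tt[-length(tt)])
    if (!length(same)) break
    i1 <- idx[same[1L]]; i2 <- idx[same[1L] + 1L]
    drop <- if (type[i1] == "p") {
      if (a[cand[i1]] >= a[cand[i2]]) i2 else i1
    } else {
      if (a[cand[i1]] <= a[cand[i2]]) i2 else i1
    }
    keep[drop] <- FALSE
  }
  cand <- cand[keep]; type <- type[keep]
  ## drop weak adjacent pairs below the prominence threshold
  repeat {
    if (length(cand) < 2L) break
    amp <- abs(diff(a[cand]))
    weak <- which(amp < prominence * rng)
    if (!length(weak)) break
    w <- weak[which.min(amp[weak])]
    cand <- cand[-c(w, w + 1L)]
    type <- type[-c(w, w + 1L)]
  }
  if (!length(cand))
    .stopf("no extrema above the prominence threshold; record a longer series")
  series@peaks <- as.integer(cand[type == "p"])
  series@valleys <- as.integer(cand[type == "v"])
  validObject(series)
  series
}

## --- scalar metrics --------------------------------------------------------

#' Contraction amplitude (occlusion ratio)
#'
#' Mean over paired cycles of `(peak - following valley) / peak`, the
#' occlusion ratio on cross-sectional area.
#'
#' @param series an [AreaTimeSeries-class] with detected extrema (run
#'   [detectExtrema] first if needed).
#' @return occlusion ratio in `[0, 1]`.
#' @seealso [areaToRadiusOcclusion] for the radius-equivalent value.
#' @export
contractionAmplitude <- function(series) {
  if (!length(series@peaks)) series <- detectExtrema(series)
  p <- series@peaks; v <- series@valleys
  a <- series@areas
  ## parabolic refinement of the extremum value: the frame grid rarely
  ## hits the true peak/trough, biasing the sampled amplitude low. Only
  ## strict local extrema are refined (plateaus are taken at face value).
  refine <- function(i, sgn) {
    if (i <= 1L || i >= length(a)) return(a[i])
    if (sgn * (a[i] - a[i - 1L]) <= 0 || sgn * (a[i] - a[i + 1L]) <= 0)
      return(a[i])
    den <- a[i - 1L] - 2 * a[i] + a[i + 1L]
    a[i] - (a[i + 1L] - a[i - 1L])^2 / (8 * den)
  }
  ratios <- vapply(p, function(pi) {
    nxt <- v[v > pi]
    if (!length(nxt)) return(NA_real_)
    pv <- refine(pi, 1); vv <- refine(nxt[1L], -1)
    (pv - vv) / pv
  }, numeric(1L))
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) .stopf("no peak-valley pair available")
  mean(ratios)
}

#' Convert an area occlusion ratio to its radius equivalent
#'
#' For a circular cross-section whose radius is scaled by `1 - A`, the
#' area scales by `(1 - A)^2`; this inverts that relation:
#' `1 - sqrt(1 - areaRatio)`.
#'
#' @param areaRatio occlusion ratio measured on areas, `[0, 1]`.
#' @return radius-equivalent occlusion ratio.
#' @export
areaToRadiusOcclusion <- function(areaRatio) 1 - sqrt(pmax(0, 1 - areaRatio))

#' Dominant contraction frequency
#'
#' Frequency of the largest non-DC spectral magnitude of the mean-removed
#' area-time series, in cycles per minute. Irregular (gated) frame times
#' are linearly resampled to their median interval first.
#'
#' @param series an [AreaTimeSeries-class] with at least 8 samples.
#' @return dominant frequency, cpm.
#' @export
contractionFrequency <- function(series) {
  a <- series@areas; tt <- series@times
  if (length(a) < 8L) .stopf("need at least 8 samples for the spectrum")
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-9 * stats::median(dts)) {
    dt <- stats::median(dts)
    grid <- seq(tt[1L], tt[length(tt)], by = dt)
    a <- stats::approx(tt, a, xout = grid)$y
  } else dt <- dts[1L]
  n <- length(a)
  sp <- Mod(stats::fft(a - mean(a)))
  half <- 2:(n %/% 2L + 1L)
  if (max(sp[half]) <= n * 1e-12 * max(abs(a), 1))
    .stopf("no non-DC spectral peak (constant series?)")
  k <- half[which.max(sp[half])]
  (k - 1L) / (n * dt) * 60
}

#' Contraction-wave propagation velocity
#'
#' Divides the distance between two cross-sections by the time delay of
#' the contraction wave between them. The delay is the lag maximizing the
#' normalized cross-correlation (among near-maximal local peaks the
#' smallest-magnitude lag is taken, resolving the periodic ambiguity),
#' refined by parabolic interpolation around the peak lag.
#'
#' @param seriesA,seriesB [AreaTimeSeries-class] objects on the same time
#'   base, `seriesB` downstream of `seriesA`.
#' @param distance distance between the cross-sections, mm; defaults to
#'   the difference of their axis positions.
#' @param minCorrelation minimal correlation at the peak lag; below it the
#'   wave is considered incoherent and an error is raised.
#' @return propagation velocity, mm/s.
#' @export
propagationVelocity <- function(seriesA, seriesB, distance = NULL,
                                minCorrelation = 0.3) {
  a <- seriesA@areas; b <- seriesB@areas
  if (length(a) != length(b) ||
      max(abs(seriesA@times - seriesB@times)) > 1e-9)
    .stopf("series must share the same time base")
  distance <- distance %||% abs(seriesB@position - seriesA@position)
  if (distance <= 0) .stopf("distance must be > 0")
  n <- length(a)
  dt <- stats::median(diff(seriesA@times))
  ## the wave travels from A (upstream) to B: the delay is sought among
  ## positive lags only, and -- the sections being closer than one
  ## wavelength -- below one contraction period, which removes the
  ## periodic-ambiguity aliases of the correlation function
  period <- tryCatch(60 / contractionFrequency(seriesA),
                     error = function(e) NA_real_)
  maxLag <- n %/% 2L
  if (is.finite(period))
    maxLag <- max(3L, min(maxLag, as.integer(ceiling(0.9 * period / dt))))
  lags <- seq.int(0L, maxLag)
  r <- vapply(lags, function(l) {
    x <- a[seq_len(n - l)]; y <- b[seq_len(n - l) + l]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
    stats::cor(x, y)
  }, numeric(1L))
  locmax <- which(diff(sign(diff(r))) < 0) + 1L
  if (!length(locmax) || r[1L] >= max(r[locmax]))
    .stopf("correlation maximal at zero lag: no positive wave delay")
  best <- max(r[locmax])
  if (best < minCorrelation)
    .stopf("correlation peak %.2f below %.2f: wave coherence violated",
           best, minCorrelation)
  pk <- locmax[r[locmax] >= 0.95 * best][1L]
  lag <- lags[pk]
  ## parabolic refinement around the peak lag
  delay <- lag
  if (is.finite(r[pk - 1L]) && is.finite(r[pk + 1L])) {
    den <- r[pk - 1L] - 2 * r[pk] + r[pk + 1L]
    if (den < 0) delay <- lag + 0.5 * (r[pk - 1L] - r[pk + 1L]) / den
  }
  delay <- delay * dt
  if (delay <= 0)
    .stopf("non-positive delay (%.3g s): wave direction violated", delay)
  distance / delay
}

#' Luminal volume per frame
#'
#' Lumen voxel count times voxel volume, in mL, per frame and
#' time-averaged.
#'
#' @param mask logical 4D lumen mask.
#' @param voxelSize (dx, dy, dz), mm.
#' @return list with `perFrame` (mL per frame) and `mean`.
#' @export
gastricVolume <- function(mask, voxelSize) {
  if (any(voxelSize <= 0)) .stopf("voxel size must be positive")
  d <- dim(mask)
  voxMl <- prod(voxelSize) / 1000
  perFrame <- vapply(seq_len(d[4L]),
                     function(t) sum(mask[, , , t]) * voxMl, numeric(1L))
  list(perFrame = perFrame, mean = mean(perFrame))
}

## --- end-to-end summary ----------------------------------------------------

#' Quantify gastric motility from a dynamic image series
#'
#' Runs the full analysis: lumen segmentation, antral axis identification,
#' cross-sectional area-time series at the requested positions, extrema
#' detection, and the four motility metrics. Amplitude and frequency are
#' pooled (mean) across positions; velocity uses the most distant
#' position pair.
#'
#' @param images an [ImageSeries-class].
#' @param hints optional 2 x 3 matrix of antral axis endpoints, mm.
#' @param positions arc-length positions of the cross-sections, mm;
#'   `NULL` places one per slice crossed by the axis, excluding the final
#'   one (nearest the corpus).
#' @param prominence extrema prominence fraction.
#' @param threshold segmentation threshold (`NULL` = Otsu).
#' @return a [MotilityMetrics-class].
#' @export
measureMotility <- function(images, hints = NULL, positions = NULL,
                            prominence = 0.1, threshold = NULL) {
  stopifnot(is(images, "ImageSeries"))
  mask <- segmentLumen(images, threshold = threshold)
  axis <- antralAxis(mask, images@voxelSize, hints = hints)
  arc <- attr(axis, "arclength")
  if (is.null(positions)) {
    pts <- arc[-c(1L, length(arc))]
    if (length(pts) > 1L) pts <- pts[-length(pts)]
    positions <- pts
  }
  if (length(positions) < 1L) .stopf("no cross-section positions")
  ats <- crossSectionAreas(mask, axis, positions, images@voxelSize,
                           images@frameTimes)
  ats <- lapply(ats, detectExtrema, prominence = prominence)
  amp <- vapply(ats, contractionAmplitude, numeric(1L))
  freq <- vapply(ats, contractionFrequency, numeric(1L))
  vel <- if (length(ats) >= 2L)
    propagationVelocity(ats[[1L]], ats[[length(ats)]]) else NA_real_
  vol <- gastricVolume(mask, images@voxelSize)
  per <- data.frame(position = vapply(ats, function(s) s@position,
                                      numeric(1L)),
                    amplitude = amp, frequency = freq)
  new("MotilityMetrics", amplitude = mean(amp),
      amplitudeRadius = areaToRadiusOcclusion(mean(amp)),
      frequency = mean(freq), velocity = vel, volume = vol$mean,
      perPosition = per)
}
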