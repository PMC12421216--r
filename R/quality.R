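#' @include AllClasses.R utils.R
NULL

.asValues <- function(x) {
  if (is(x, "ImageSeries")) x@values else x
}

.checkSameShape <- function(test, ref) {
  if (!identical(dim(test), dim(ref)))
    .stopf("test and reference images must have the same shape")
}

#' Normalize an image series to [0, 1]
#'
#' One global (series-wide) affine scaling `(x - min) / (max - min)`, so
#' temporal intensity dynamics are preserved across frames. Metrics are
#' computed on normalized images when emulating the evaluation protocol.
#'
#' @param images an [ImageSeries-class] (or bare array).
#' @return object of the same kind, spanning `[0, 1]`.
#' @export
normalize01 <- function(images) {
  v <- .asValues(images)
  rng <- range(v)
  if (diff(rng) == 0)
    .stopf("cannot normalize a constant series (undefined scaling)")
  vn <- (v - rng[1L]) / diff(rng)
  if (is(images, "ImageSeries")) {
    images@values <- vn
    images
  } else vn
}

#' Relative error between two image series
#'
#' The L2 norm of the intensity differences between the vectorized images
#' divided by the L2 norm of the reference.
#'
#' @param test,ref same-shape [ImageSeries-class] objects or arrays;
#'   `ref` must not be all-zero.
#' @return dimensionless RE >= 0 (0 iff identical).
#' @export
relativeError <- function(test, ref) {
  tv <- .asValues(test); rv <- .asValues(ref)
  .checkSameShape(tv, rv)
  nr <- sqrt(sum(rv^2))
  if (nr == 0) .stopf("reference has zero norm")
  sqrt(sum((tv - rv)^2)) / nr
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(dataRange^2 / MSE)`; identical images return `Inf`.
#'
#' @param test,ref same-shape images or arrays.
#' @param dataRange intensity range of the data; defaults to the range of
#'   the reference.
#' @return PSNR in dB.
#' @export
psnr <- function(test, ref, dataRange = NULL) {
  tv <- .asValues(test); rv <- .asValues(ref)
  .checkSameShape(tv, rv)
  mse <- mean((tv - rv)^2)
  if (mse == 0) return(Inf)
  dr <- dataRange %||% diff(range(rv))
  10 * log10(dr^2 / mse)
}

## window sums over all full w x w windows of a matrix, via integral image
.winSums <- function(m, w) {
  cs <- apply(apply(m, 2L, cumsum), 1L, cumsum)   # transposed integral
  cs <- t(cs)
  nr <- nrow(m); nc <- ncol(m)
  Z <- matrix(0, nr + 1L, nc + 1L)
  Z[-1L, -1L] <- cs
  i <- seq_len(nr - w + 1L); j <- seq_len(nc - w + 1L)
  Z[i + w, j + w, drop = FALSE] - Z[i, j + w, drop = FALSE] -
    Z[i + w, j, drop = FALSE] + Z[i, j, drop = FALSE]
}

.ssimPlane <- function(x, y, w, C1, C2) {
  n <- w * w
  mx <- .winSums(x, w) / n
  my <- .winSums(y, w) / n
  vx <- .winSums(x * x, w) / n - mx^2
  vy <- .winSums(y * y, w) / n - my^2
  cxy <- .winSums(x * y, w) / n - mx * my
  ## unbiased (n-1) normalization of (co)variances, as in the standard
  ## reference implementation
  f <- n / (n - 1)
  vx <- vx * f; vy <- vy * f; cxy <- cxy * f
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

#' Structural similarity index
#'
#' Mean local SSIM (Wang et al. formulation, uniform square window) over
#' each 2D slice/frame plane, averaged across the series. Local statistics
#' use only windows fully inside the plane.
#'
#' @param test,ref same-shape images or arrays.
#' @param window window side in pixels (default 7).
#' @param K stabilizing constants `(K1, K2)`; `C_i = (K_i * dataRange)^2`.
#' @param dataRange intensity range; defaults to the range of the
#'   reference.
#' @return SSIM in `[-1, 1]`; 1 iff identical (non-degenerate images).
#' @export
ssim <- function(test, ref, window = 7L, K = c(0.01, 0.03),
                 dataRange = NULL) {
  tv <- .asValues(test); rv <- .asValues(ref)
  .checkSameShape(tv, rv)
  d <- dim(tv)
  if (is.null(d)) { tv <- matrix(tv); rv <- matrix(rv); d <- dim(tv) }
  if (window > min(d[1:2]))
    .stopf("SSIM window (%d) larger than the image plane", window)
  dr <- dataRange %||% diff(range(rv))
  C1 <- (K[1L] * dr)^2; C2 <- (K[2L] * dr)^2
  if (length(d) == 2L)
    return(.ssimPlane(tv, rv, window, C1, C2))
  planes <- expand.grid(s = seq_len(d[3L]),
                        t = seq_len(if (length(d) >= 4L) d[4L] else 1L))
  vals <- mapply(function(s, t) {
    if (length(d) >= 4L)
      .ssimPlane(tv[, , s, t], rv[, , s, t], window, C1, C2)
    else .ssimPlane(tv[, , s], rv[, , s], window, C1, C2)
  }, planes$s, planes$t)
  mean(vals)
}

#' Maximum intensity projection
#'
#' Per-frame maximum over the chosen spatial axis (default: across
#' slices), the standard whole-stomach visualization.
#'
#' @param images an [ImageSeries-class] or 4D array.
#' @param axis spatial axis to project over (1 = x, 2 = y, 3 = slice).
#' @return array with the projected axis dropped to length 1 retained as
#'   (dim1, dim2, time); a single-slice input projected over slices is
#'   returned unchanged in content.
#' @export
mip <- function(images, axis = 3L) {
  v <- .asValues(images)
  if (length(dim(v)) != 4L) .stopf("mip expects a 4D series")
  if (!axis %in% 1:3) .stopf("axis must be 1, 2 or 3")
  apply(v, setdiff(1:4, axis), max)
}

#' Pearson correlation
#'
#' Product-moment correlation between two equally sized sets of
#' measurements (used for the volume-agreement check).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 3L) .stopf("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("correlation undefined for constant input")
  stats::cor(x, y, method = "pearson")
}

#' Image-quality summary against a fully sampled reference
#'
#' Convenience wrapper computing RE, SSIM and PSNR, after jointly
#' normalizing both series to `[0, 1]` (each by its own global range)
#' when `normalize = TRUE`, emulating the evaluation protocol.
#'
#' @param test,ref same-shape [ImageSeries-class] objects.
#' @param normalize normalize each series to `[0, 1]` first.
#' @param ssimWindow SSIM window side.
#' @return named list with elements `re`, `ssim`, `psnr`.
#' @export
imageQuality <- function(test, ref, normalize = TRUE, ssimWindow = 7L) {
  if (normalize) {
    test <- normalize01(test)
    ref <- normalize01(ref)
  }
  list(re = relativeError(test, ref),
       ssim = ssim(test, ref, window = ssimWindow, dataRange = 1),
       psnr = psnr(test, ref, dataRange = 1))
}
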