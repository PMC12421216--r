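#' @include AllClasses.R utils.R
NULL

.sidecarPath <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write a dynamic image series to NIfTI-1
#'
#' The 4D data array goes into the NIfTI file with voxel spacing in the
#' header; frame times and provenance go into a JSON sidecar next to it.
#'
#' @param images an [ImageSeries-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeImageSeries <- function(images, path) {
  stopifnot(is(images, "ImageSeries"))
  ft <- images@frameTimes
  dt <- if (length(ft) > 1L) stats::median(diff(ft)) else 1
  img <- RNifti::asNifti(images@values)
  RNifti::pixdim(img) <- c(images@voxelSize, dt)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(frameTimes = ft,
                            provenance = images@provenance),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dynamic image series from NIfTI-1
#'
#' Requires a 4D file; frame times are taken from the JSON sidecar when
#' present, otherwise derived from the header repetition time with a
#' warning.
#'
#' @param path NIfTI path written by [writeImageSeries] (or any 4D
#'   NIfTI-1 file with spacing in its header).
#' @return an [ImageSeries-class].
#' @export
readImageSeries <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    .stopf("expected a 4D image series, got %d dimension(s); %s",
           length(d), "write dynamic data as (x, y, slice, time)")
  pd <- RNifti::pixdim(img)
  if (any(pd[1:3] <= 0))
    .stopf("missing voxel spacing in the NIfTI header; set pixdim")
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    ft <- as.numeric(meta$frameTimes)
    prov <- meta$provenance %||% "file"
  } else {
    tr <- if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1
    .warnf("no sidecar found; deriving frame times from header TR = %g s",
           tr)
    ft <- seq(0, by = tr, length.out = d[4L])
    prov <- "file"
  }
  new("ImageSeries", values = array(as.numeric(img), d),
      voxelSize = as.numeric(pd[1:3]), frameTimes = ft, provenance = prov)
}

## k-space container: <prefix>_real.nii / <prefix>_imag.nii hold the real
## and imaginary parts of the (kx, ky, slice, time) array; the JSON
## sidecar <prefix>_meta.json holds the line mask, frame times, voxel size
## and acquisition attributes, with a schema version.

#' Write a k-space series to the package's on-disk container
#'
#' A NIfTI pair (real and imaginary parts) plus a JSON sidecar carrying
#' the sampling mask and acquisition attributes. NIfTI has no native
#' complex/mask convention, so the container keeps the array data in two
#' widely readable NIfTI files and the bookkeeping in structured text.
#'
#' @param kspace a [KSpaceSeries-class].
#' @param prefix output path prefix (files `<prefix>_real.nii`,
#'   `<prefix>_imag.nii`, `<prefix>_meta.json`).
#' @return `prefix`, invisibly.
#' @export
writeKSpace <- function(kspace, prefix) {
  stopifnot(is(kspace, "KSpaceSeries"))
  RNifti::writeNifti(RNifti::asNifti(Re(kspace@data)),
                     paste0(prefix, "_real.nii"))
  RNifti::writeNifti(RNifti::asNifti(Im(kspace@data)),
                     paste0(prefix, "_imag.nii"))
  jsonlite::write_json(
    list(schema = "gastroKT-kspace-1",
         maskDim = dim(kspace@mask),
         mask = as.integer(kspace@mask),
         voxelSize = kspace@voxelSize,
         frameTimes = kspace@frameTimes,
         acqParams = kspace@acqParams),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a k-space series from the on-disk container
#'
#' Inverse of [writeKSpace]; a container without a mask entry is treated
#' as fully sampled with a warning.
#'
#' @param prefix path prefix used at write time.
#' @return a [KSpaceSeries-class].
#' @export
readKSpace <- function(prefix) {
  re <- RNifti::readNifti(paste0(prefix, "_real.nii"))
  im <- RNifti::readNifti(paste0(prefix, "_imag.nii"))
  if (!identical(dim(re), dim(im)))
    .stopf("real/imaginary parts disagree in shape")
  if (length(dim(re)) != 4L)
    .stopf("k-space container must hold 4D (kx, ky, slice, time) data")
  d <- dim(re)
  metaPath <- paste0(prefix, "_meta.json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else list()
  if (is.null(meta$mask)) {
    .warnf("no sampling mask in container; assuming fully sampled")
    mask <- array(TRUE, d[2:4])
  } else {
    mask <- array(as.integer(meta$mask) > 0L,
                  as.integer(meta$maskDim %||% d[2:4]))
  }
  ft <- as.numeric(meta$frameTimes %||% (seq_len(d[4L]) - 1))
  vs <- as.numeric(meta$voxelSize %||% c(1, 1, 1))
  new("KSpaceSeries",
      data = array(complex(real = as.numeric(re),
                           imaginary = as.numeric(im)), d),
      mask = mask, voxelSize = vs, frameTimes = ft,
      acqParams = as.list(meta$acqParams %||% list()))
}

#' Read a run configuration from YAML
#'
#' Parses a structured config file with optional `phantom`, `tissue`,
#' `frames`, `sampling`, `recon`, `metrics` and `analysis` sections; any
#' omitted field falls back to the package default. Every stage's
#' parameters are validated before anything runs.
#'
#' @param path YAML file path.
#' @return a validated [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantomConfig, y$phantom %||% list())
  ti <- do.call(tissueProperties, y$tissue %||% list())
  fr <- y$frames %||% list()
  ft <- if (!is.null(fr$times)) as.numeric(fr$times) else
    defaultFrameTimes(n = fr$nFrames %||% 60L, dt = fr$dt %||% 2)
  sa <- y$sampling %||% list()
  rc <- y$recon %||% list()
  me <- y$metrics %||% list()
  an <- y$analysis %||% list()
  runConfig(phantom = ph, tissue = ti, frameTimes = ft,
            reduction = sa$reduction %||% 3L, nACS = sa$nACS %||% 12L,
            kxHalfWidth = rc$kxHalfWidth %||% 2L,
            kyHalfWidth = rc$kyHalfWidth %||% 2L,
            ssimWindow = me$ssimWindow %||% 7L,
            positions = as.numeric(an$positions %||% numeric()),
            seed = y$seed %||% 1L, outDir = y$outDir %||% "")
}
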