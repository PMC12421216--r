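#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the toolkit's containers: `intensities`
#' returns the image array, `kspaceData` the complex k-space array,
#' `samplingMask` the line mask, `voxelSize`/`frameTimes`/`nFrames` the
#' shared spatiotemporal metadata, `areas` the area-time values, and
#' `peakIndices`/`valleyIndices` the detected extrema.
#'
#' @param object one of the package's S4 containers.
#' @return the slot value; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("kspaceData", function(object) standardGeneric("kspaceData"))

#' @rdname accessors
#' @export
setGeneric("samplingMask", function(object) standardGeneric("samplingMask"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("areas", function(object) standardGeneric("areas"))

#' @rdname accessors
#' @export
setGeneric("peakIndices", function(object) standardGeneric("peakIndices"))

#' @rdname accessors
#' @export
setGeneric("valleyIndices", function(object) standardGeneric("valleyIndices"))

#' @rdname accessors
#' @export
setGeneric("reduction", function(object) standardGeneric("reduction"))

#' @rdname accessors
#' @export
setGeneric("acsLines", function(object) standardGeneric("acsLines"))
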