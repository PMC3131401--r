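#' @rdname Spectrum-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("transmitterFrequency",
           function(object) standardGeneric("transmitterFrequency"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("referencePpm", function(object) standardGeneric("referencePpm"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumRole", function(object) standardGeneric("spectrumRole"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumDomain", function(object) standardGeneric("spectrumDomain"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("nAverages", function(object) standardGeneric("nAverages"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("echoTime", function(object) standardGeneric("echoTime"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("repetitionTime", function(object) standardGeneric("repetitionTime"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("ppmAxis", function(object) standardGeneric("ppmAxis"))

#' Voxel volume in mm^3
#'
#' @param object a [VoxelGeometry-class] or [Spectrum-class].
#' @return volume in mm^3 (product of the three edge lengths).
#' @export
setGeneric("volume", function(object) standardGeneric("volume"))

#' @rdname PeakFit-accessors
#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))

#' @rdname PeakFit-accessors
#' @export
setGeneric("peakCenter", function(object) standardGeneric("peakCenter"))

#' @rdname PeakFit-accessors
#' @export
setGeneric("linewidth", function(object) standardGeneric("linewidth"))

#' @rdname PeakFit-accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
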