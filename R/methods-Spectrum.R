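#' Accessors for Spectrum objects
#'
#' Slot access for [Spectrum-class]; user code should use these rather than
#' `@`.
#'
#' @param object a [Spectrum-class].
#' @return the corresponding slot value; `ppmAxis()` returns the ppm value of
#'   every frequency-domain sample in ascending frequency order (so in
#'   ascending ppm; NMR display convention reverses the axis).
#' @name Spectrum-accessors
NULL

#' @rdname Spectrum-accessors
#' @export
setMethod("samples", "Spectrum", function(object) object@samples)

#' @rdname Spectrum-accessors
#' @export
setMethod("nPoints", "Spectrum", function(object) length(object@samples))

#' @rdname Spectrum-accessors
#' @export
setMethod("bandwidth", "Spectrum", function(object) object@bandwidth)

#' @rdname Spectrum-accessors
#' @export
setMethod("transmitterFrequency", "Spectrum",
          function(object) object@transmitterFrequency)

#' @rdname Spectrum-accessors
#' @export
setMethod("referencePpm", "Spectrum", function(object) object@referencePpm)

#' @rdname Spectrum-accessors
#' @export
setMethod("spectrumRole", "Spectrum", function(object) object@role)

#' @rdname Spectrum-accessors
#' @export
setMethod("spectrumDomain", "Spectrum", function(object) object@domain)

#' @rdname Spectrum-accessors
#' @export
setMethod("nAverages", "Spectrum", function(object) object@nAverages)

#' @rdname Spectrum-accessors
#' @export
setMethod("echoTime", "Spectrum", function(object) object@echoTime)

#' @rdname Spectrum-accessors
#' @export
setMethod("repetitionTime", "Spectrum", function(object) object@repetitionTime)

#' @rdname Spectrum-accessors
#' @export
setMethod("geometry", "Spectrum", function(object) object@geometry)

#' @rdname Spectrum-accessors
#' @export
setMethod("ppmAxis", "Spectrum", function(object) {
  n <- length(object@samples)
  freq <- (seq_len(n) - 1L - floor(n / 2)) * object@bandwidth / n
  object@referencePpm + freq / object@transmitterFrequency
})

#' @export
#' @describeIn volume product of the three voxel edges.
setMethod("volume", "VoxelGeometry",
          function(object) object@dimX * object@dimY * object@dimZ)

#' @export
#' @describeIn volume volume of the spectrum's voxel.
setMethod("volume", "Spectrum", function(object) volume(object@geometry))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s, %s domain): %d points\n", object@role,
              object@domain, length(object@samples)))
  cat(sprintf("  bandwidth %.6g Hz | f0 %.6g MHz | center %.6g ppm\n",
              object@bandwidth, object@transmitterFrequency,
              object@referencePpm))
  cat(sprintf("  TR %.6g ms | TE %.6g ms | %d averages | voxel %.6g mm^3\n",
              object@repetitionTime, object@echoTime, object@nAverages,
              volume(object@geometry)))
  invisible(NULL)
})

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %.6g x %.6g x %.6g mm (%.6g mm^3)\n",
              object@dimX, object@dimY, object@dimZ, volume(object)))
  invisible(NULL)
})

#' Accessors for PeakFit objects
#'
#' @param object a [PeakFit-class].
#' @return the corresponding fitted quantity.
#' @name PeakFit-accessors
NULL

#' @rdname PeakFit-accessors
#' @export
setMethod("peakArea", "PeakFit", function(object) object@area)

#' @rdname PeakFit-accessors
#' @export
setMethod("peakCenter", "PeakFit", function(object) object@center)

#' @rdname PeakFit-accessors
#' @export
setMethod("linewidth", "PeakFit", function(object) object@linewidthFwhm)

#' @rdname PeakFit-accessors
#' @export
setMethod("converged", "PeakFit", function(object) object@converged)

#' @rdname PeakFit-accessors
#' @export
setMethod("converged", "SigmoidModel", function(object) object@converged)

setMethod("show", "PeakFit", function(object) {
  cat(sprintf("PeakFit (%s): center %.4f ppm | FWHM %.3f Hz | area %.6g\n",
              object@lineshape, object@center, object@linewidthFwhm,
              object@area))
  cat(sprintf("  rmse %.4g | converged: %s\n", object@rmse, object@converged))
  invisible(NULL)
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel: carnosine (mM) ~ percent type-II area\n")
  cat(sprintf("  slope %.5g mM/%% | intercept %.5g mM | n = %d\n",
              object@slope, object@intercept, object@n))
  cat(sprintf("  r = %.3f | p = %.4g | residual SD %.4g mM\n", object@r,
              object@pValue, object@residualSd))
  invisible(NULL)
})

setMethod("show", "SigmoidModel", function(object) {
  cat("SigmoidModel: z(d) = bottom + (top - bottom)/(1 + (d/d50)^hill)\n")
  cat(sprintf("  top %.3f | bottom %.3f | d50 %.4g m | hill %.3f\n",
              object@top, object@bottom, object@d50, object@hill))
  if (!is.na(object@rSquared))
    cat(sprintf("  R^2 = %.4f | converged: %s\n", object@rSquared,
                object@converged))
  invisible(NULL)
})

setMethod("show", "ReferenceStats", function(object) {
  cat(sprintf("ReferenceStats (%s): %.3f +/- %.3f mM (n = %d)\n", object@sex,
              object@mean, object@sd, object@n))
  invisible(NULL)
})

#' Plot a spectrum
#'
#' Frequency-domain spectra are drawn against ppm with the axis decreasing
#' left-to-right (NMR convention); time-domain FIDs against time in seconds.
#'
#' @param x a [Spectrum-class].
#' @param y ignored.
#' @param part `"real"`, `"imaginary"` or `"magnitude"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
setMethod("plot", signature(x = "Spectrum", y = "missing"),
  function(x, y, part = c("real", "imaginary", "magnitude"), ...) {
    part <- match.arg(part)
    v <- switch(part, real = Re(x@samples), imaginary = Im(x@samples),
                magnitude = Mod(x@samples))
    if (x@domain == "frequency") {
      ppm <- ppmAxis(x)
      graphics::plot(ppm, v, type = "l", xlim = rev(range(ppm)),
                     xlab = "chemical shift (ppm)", ylab = part, ...)
    } else {
      t <- (seq_along(v) - 1) / x@bandwidth
      graphics::plot(t, v, type = "l", xlab = "time (s)", ylab = part, ...)
    }
    invisible(NULL)
  })
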