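#' @import methods
NULL

.validLineshapes <- c("lorentzian", "gaussian")
.validRoles <- c("muscle", "phantom")
.validDomains <- c("time", "frequency")
.validSexes <- c("male", "female")
.validGroups <- c("control", "talent", "elite", "ex_athlete")
.validCategories <- c("explosive", "endurance", "mixed", "control")

#' Voxel geometry of a spectroscopy acquisition
#'
#' Dimensions of the rectangular spectroscopy voxel in mm. The volume is
#' derived, never stored, so it can not fall out of sync with the dimensions.
#'
#' @slot dimX,dimY,dimZ voxel edge lengths in mm; all strictly positive.
#' @seealso [volume()]
#' @export
setClass("VoxelGeometry",
  representation(dimX = "numeric", dimY = "numeric", dimZ = "numeric"))

setValidity("VoxelGeometry", function(object) {
  d <- c(object@dimX, object@dimY, object@dimZ)
  if (length(d) != 3L || anyNA(d) || any(d <= 0))
    return("all voxel dimensions must be single positive numbers (mm)")
  TRUE
})

#' Construct a VoxelGeometry
#'
#' @param dimX,dimY,dimZ voxel edge lengths in mm.
#' @return A [VoxelGeometry-class] object.
#' @examples
#' volume(VoxelGeometry(40, 12, 28))  # 13440 mm^3, i.e. 13.44 ml
#' @export
VoxelGeometry <- function(dimX, dimY, dimZ) {
  new("VoxelGeometry", dimX = as.numeric(dimX), dimY = as.numeric(dimY),
      dimZ = as.numeric(dimZ))
}

#' Single-voxel MRS spectrum
#'
#' One acquisition (muscle or external reference phantom): the complex signal
#' plus the acquisition metadata needed for quantification. The signal is
#' either a time-domain free induction decay (FID) or a frequency-domain
#' spectrum, flagged by `domain`. Frequency-domain samples are stored in
#' ascending frequency order; the ppm axis is derived from `bandwidth`,
#' `transmitterFrequency` and `referencePpm` (the ppm value assigned to the
#' spectral center, water-referenced 4.70 ppm by convention).
#'
#' @slot samples complex vector (FID or spectrum).
#' @slot bandwidth spectral bandwidth in Hz (> 0).
#' @slot transmitterFrequency transmitter frequency in MHz (> 0); converts
#'   ppm offsets to Hz.
#' @slot referencePpm ppm value at the spectral center.
#' @slot echoTime,repetitionTime PRESS TE and TR in ms.
#' @slot nAverages number of accumulated excitations (>= 1).
#' @slot role `"muscle"` or `"phantom"`.
#' @slot domain `"time"` or `"frequency"`.
#' @slot geometry [VoxelGeometry-class] of the voxel.
#' @export
setClass("Spectrum",
  representation(samples = "complex", bandwidth = "numeric",
                 transmitterFrequency = "numeric", referencePpm = "numeric",
                 echoTime = "numeric", repetitionTime = "numeric",
                 nAverages = "integer", role = "character",
                 domain = "character", geometry = "VoxelGeometry"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "empty spectrum: 'samples' must contain at least one point")
  if (length(object@bandwidth) != 1L || is.na(object@bandwidth) ||
      object@bandwidth <= 0)
    msg <- c(msg, "'bandwidth' must be a single positive number (Hz)")
  if (length(object@transmitterFrequency) != 1L ||
      is.na(object@transmitterFrequency) || object@transmitterFrequency <= 0)
    msg <- c(msg, "'transmitterFrequency' must be a single positive number (MHz)")
  if (length(object@nAverages) != 1L || is.na(object@nAverages) ||
      object@nAverages < 1L)
    msg <- c(msg, "'nAverages' must be a single integer >= 1")
  if (!object@role %in% .validRoles)
    msg <- c(msg, sprintf("'role' must be one of: %s",
                          paste(.validRoles, collapse = ", ")))
  if (!object@domain %in% .validDomains)
    msg <- c(msg, sprintf("'domain' must be one of: %s",
                          paste(.validDomains, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param samples complex (or numeric, promoted) signal vector.
#' @param bandwidth spectral bandwidth in Hz.
#' @param transmitterFrequency transmitter frequency in MHz.
#' @param referencePpm ppm value at the spectral center (default 4.70,
#'   the water resonance).
#' @param echoTime echo time TE in ms.
#' @param repetitionTime repetition time TR in ms.
#' @param nAverages number of excitations.
#' @param role `"muscle"` or `"phantom"`.
#' @param domain `"time"` or `"frequency"`.
#' @param geometry a [VoxelGeometry-class].
#' @return A [Spectrum-class] object.
#' @export
Spectrum <- function(samples, bandwidth, transmitterFrequency,
                     referencePpm = 4.70, echoTime = 30,
                     repetitionTime = 2000, nAverages = 1L,
                     role = "muscle", domain = "time",
                     geometry = VoxelGeometry(40, 12, 28)) {
  new("Spectrum", samples = as.complex(samples),
      bandwidth = as.numeric(bandwidth),
      transmitterFrequency = as.numeric(transmitterFrequency),
      referencePpm = as.numeric(referencePpm),
      echoTime = as.numeric(echoTime),
      repetitionTime = as.numeric(repetitionTime),
      nAverages = as.integer(nAverages), role = role, domain = domain,
      geometry = geometry)
}

#' Spectral peak description used by the simulator
#'
#' @slot center resonance position in ppm.
#' @slot amplitude signal amplitude per mM per mm^3 (>= 0).
#' @slot linewidthFwhm full width at half maximum in Hz (> 0).
#' @slot lineshape `"lorentzian"` or `"gaussian"`.
#' @export
setClass("PeakSpec",
  representation(center = "numeric", amplitude = "numeric",
                 linewidthFwhm = "numeric", lineshape = "character"))

setValidity("PeakSpec", function(object) {
  msg <- character()
  if (length(object@linewidthFwhm) != 1L || is.na(object@linewidthFwhm) ||
      object@linewidthFwhm <= 0)
    msg <- c(msg, "'linewidthFwhm' must be a single positive number (Hz)")
  if (length(object@amplitude) != 1L || is.na(object@amplitude) ||
      object@amplitude < 0)
    msg <- c(msg, "'amplitude' must be a single non-negative number")
  if (!object@lineshape %in% .validLineshapes)
    msg <- c(msg, sprintf("'lineshape' must be one of: %s",
                          paste(.validLineshapes, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSpec
#'
#' @param center ppm position.
#' @param amplitude signal amplitude per mM per mm^3.
#' @param linewidthFwhm FWHM in Hz.
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return A [PeakSpec-class].
#' @export
PeakSpec <- function(center, amplitude = 1, linewidthFwhm = 10,
                     lineshape = "lorentzian") {
  new("PeakSpec", center = as.numeric(center),
      amplitude = as.numeric(amplitude),
      linewidthFwhm = as.numeric(linewidthFwhm), lineshape = lineshape)
}

#' Result of a model-based peak fit
#'
#' Produced by [fitPeak()]. `area` is the analytic integral of the fitted
#' lineshape (the quantity entering absolute quantification as S), not a
#' numeric sum over the window.
#'
#' @slot center fitted position in ppm.
#' @slot linewidthFwhm fitted FWHM in Hz.
#' @slot area analytic area of the fitted lineshape (signal units).
#' @slot lineshape model used.
#' @slot baselineCoefficients polynomial baseline coefficients over the
#'   fitted window (ascending degree, on a window-scaled abscissa).
#' @slot rmse root-mean-square fit residual (signal units).
#' @slot converged logical convergence flag; honest, never silently forced.
#' @slot message solver diagnostic.
#' @export
setClass("PeakFit",
  representation(center = "numeric", linewidthFwhm = "numeric",
                 area = "numeric", lineshape = "character",
                 baselineCoefficients = "numeric", rmse = "numeric",
                 converged = "logical", message = "character"))

setValidity("PeakFit", function(object) {
  msg <- character()
  if (object@area < 0) msg <- c(msg, "'area' must be >= 0")
  if (object@rmse < 0) msg <- c(msg, "'rmse' must be >= 0")
  if (isTRUE(object@converged) && object@linewidthFwhm <= 0)
    msg <- c(msg, "'linewidthFwhm' must be > 0 for a converged fit")
  if (length(msg)) msg else TRUE
})

#' Inputs of the absolute quantification formula
#'
#' Every symbol of the external-reference concentration formula: the phantom
#' concentration, the fitted peak areas, the voxel volumes, the T1/T2
#' relaxation times with the sequence timings that turn them into correction
#' factors, and the absolute temperatures of muscle and phantom.
#'
#' Units are validated at construction: TR/TE/T1/T2 in ms, temperatures in K,
#' volumes in mm^3, concentrations in mM.
#'
#' @slot cR phantom carnosine concentration (mM).
#' @slot sM,sR fitted peak areas of muscle and phantom (signal units);
#'   sM may be 0, sR must be > 0.
#' @slot vM,vR voxel volumes (mm^3).
#' @slot t1M,t2M,t1R,t2R relaxation times (ms).
#' @slot tr,te repetition and echo time (ms); TE < TR.
#' @slot tempM,tempR absolute temperatures (K).
#' @export
setClass("QuantificationInputs",
  representation(cR = "numeric", sM = "numeric", sR = "numeric",
                 vM = "numeric", vR = "numeric",
                 t1M = "numeric", t2M = "numeric",
                 t1R = "numeric", t2R = "numeric",
                 tr = "numeric", te = "numeric",
                 tempM = "numeric", tempR = "numeric"))

setValidity("QuantificationInputs", function(object) {
  msg <- character()
  pos <- c(cR = object@cR, vM = object@vM, vR = object@vR, t1M = object@t1M,
           t2M = object@t2M, t1R = object@t1R, t2R = object@t2R,
           tr = object@tr, te = object@te, tempM = object@tempM,
           tempR = object@tempR)
  bad <- names(pos)[is.na(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, sprintf("strictly positive value required for: %s",
                          paste(bad, collapse = ", ")))
  if (is.na(object@sM) || object@sM < 0)
    msg <- c(msg, "'sM' must be >= 0")
  if (is.na(object@sR))
    msg <- c(msg, "'sR' must be a number")
  if (!anyNA(c(object@te, object@tr)) && object@te >= object@tr)
    msg <- c(msg, "'te' must be smaller than 'tr'")
  if (length(msg)) msg else TRUE
})

#' Construct QuantificationInputs
#'
#' @param cR phantom concentration, mM (20 mM by convention).
#' @param sM,sR fitted muscle and phantom peak areas.
#' @param vM,vR muscle and phantom voxel volumes, mm^3.
#' @param t1M,t2M,t1R,t2R relaxation times, ms.
#' @param tr,te repetition and echo time, ms.
#' @param tempM,tempR absolute temperatures, K.
#' @return A [QuantificationInputs-class].
#' @export
QuantificationInputs <- function(cR, sM, sR, vM, vR, t1M, t2M, t1R, t2R,
                                 tr, te, tempM, tempR) {
  new("QuantificationInputs", cR = as.numeric(cR), sM = as.numeric(sM),
      sR = as.numeric(sR), vM = as.numeric(vM), vR = as.numeric(vR),
      t1M = as.numeric(t1M), t2M = as.numeric(t2M), t1R = as.numeric(t1R),
      t2R = as.numeric(t2R), tr = as.numeric(tr), te = as.numeric(te),
      tempM = as.numeric(tempM), tempR = as.numeric(tempR))
}

#' Linear carnosine vs percent type-II fiber area calibration
#'
#' Ordinary least squares of carnosine (mM, response) on percent type-II
#' fiber area (predictor), as in the biopsy calibration. Fiber-type estimates
#' for new subjects come from inverse regression on this single object.
#'
#' @slot slope mM per percent type-II area.
#' @slot intercept mM.
#' @slot r Pearson correlation.
#' @slot pValue two-sided p from the t transform (n - 2 df).
#' @slot n number of calibration pairs (>= 3).
#' @slot residualSd residual standard deviation, mM (n - 2 denominator).
#' @slot xMean,yMean means of predictor (%) and response (mM); the fitted
#'   line passes through this centroid.
#' @slot sxx centered sum of squares of the predictor (needed for intervals).
#' @export
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric", r = "numeric",
                 pValue = "numeric", n = "integer", residualSd = "numeric",
                 xMean = "numeric", yMean = "numeric", sxx = "numeric"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (object@n < 3L) msg <- c(msg, "'n' must be >= 3")
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "'r' must lie in [-1, 1]")
  if (object@residualSd < 0) msg <- c(msg, "'residualSd' must be >= 0")
  ctr <- object@intercept + object@slope * object@xMean
  if (is.finite(ctr) && abs(ctr - object@yMean) >
      1e-8 * max(1, abs(object@yMean)))
    msg <- c(msg, "fitted line must pass through (xMean, yMean)")
  if (length(msg)) msg else TRUE
})

#' Four-parameter logistic model of Z-score vs running distance
#'
#' z(d) = bottom + (top - bottom) / (1 + (d / d50)^hill), decreasing in d for
#' top > bottom and hill > 0; on a log10 distance axis this is the familiar
#' sigmoid with midpoint at d50 (in meters).
#'
#' @slot top,bottom asymptotic Z-scores at short and long distance.
#' @slot d50 midpoint distance in m (> 0).
#' @slot hill slope parameter on log10(distance).
#' @slot rSquared coefficient of determination on the fitted points.
#' @slot converged logical.
#' @export
setClass("SigmoidModel",
  representation(top = "numeric", bottom = "numeric", d50 = "numeric",
                 hill = "numeric", rSquared = "numeric",
                 converged = "logical"))

setValidity("SigmoidModel", function(object) {
  msg <- character()
  if (is.na(object@d50) || object@d50 <= 0)
    msg <- c(msg, "'d50' must be > 0 (meters)")
  if (!is.na(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "'rSquared' must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SigmoidModel
#'
#' @param top,bottom asymptotic Z-scores.
#' @param d50 midpoint distance, m.
#' @param hill slope parameter.
#' @param rSquared fit statistic (NA for a ground-truth model).
#' @param converged logical.
#' @return A [SigmoidModel-class].
#' @export
SigmoidModel <- function(top, bottom, d50, hill, rSquared = NA_real_,
                         converged = TRUE) {
  new("SigmoidModel", top = as.numeric(top), bottom = as.numeric(bottom),
      d50 = as.numeric(d50), hill = as.numeric(hill),
      rSquared = as.numeric(rSquared), converged = converged)
}

#' Sex-specific reference statistics for Z-scoring
#'
#' Mean and SD of the same-sex reference (control) population; Z-scores are
#' computed within sex because men have systematically higher muscle
#' carnosine than women.
#'
#' @slot sex `"male"` or `"female"`.
#' @slot mean,sd reference mean and SD, mM (sd > 0).
#' @slot n reference sample size (>= 2).
#' @export
setClass("ReferenceStats",
  representation(sex = "character", mean = "numeric", sd = "numeric",
                 n = "integer"))

setValidity("ReferenceStats", function(object) {
  msg <- character()
  if (!object@sex %in% .validSexes)
    msg <- c(msg, sprintf("'sex' must be one of: %s",
                          paste(.validSexes, collapse = ", ")))
  if (is.na(object@sd) || object@sd <= 0)
    msg <- c(msg, "'sd' must be > 0")
  if (is.na(object@n) || object@n < 2L)
    msg <- c(msg, "'n' must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct ReferenceStats
#'
#' @param sex `"male"` or `"female"`.
#' @param mean,sd reference mean and SD in mM.
#' @param n reference sample size.
#' @return A [ReferenceStats-class].
#' @export
ReferenceStats <- function(sex, mean, sd, n) {
  new("ReferenceStats", sex = sex, mean = as.numeric(mean),
      sd = as.numeric(sd), n = as.integer(n))
}
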