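#' Synthesize a PRESS free induction decay with known ground truth
#'
#' Builds a complex time-domain FID as a sum of exponentially (Lorentzian) or
#' Gaussian-decaying resonances plus optional complex white noise. The signal
#' is scaled so that the analytic absorption-mode area of peak k in the
#' frequency domain equals
#' `amplitude_k * concentration_k * volume * n_averages`
#' (see [truePeakArea()]), i.e. noiseless peak areas are exactly proportional
#' to concentration times voxel volume — the property absolute quantification
#' relies on.
#'
#' Sampling follows the acquisition block: `n_points` samples at
#' `1/bandwidth_hz` spacing. Noise is complex Gaussian with per-channel
#' standard deviation `noiseSd * sqrt(n_averages)`, so that signal-to-noise
#' grows as the square root of the number of averages, as for summed
#' acquisitions.
#'
#' @param peaks list of [PeakSpec-class] (may be empty for a noise-only run).
#' @param concentrations numeric, mM, one per peak.
#' @param geometry [VoxelGeometry-class] of the simulated voxel.
#' @param acq acquisition constants: a named list with
#'   `repetition_time_ms`, `echo_time_ms`, `n_points`, `bandwidth_hz`,
#'   `n_averages`, `transmitter_frequency_mhz`, `reference_ppm`
#'   (as in `defaultConfig()$acquisition`).
#' @param noiseSd per-average complex-channel noise SD (signal units); 0
#'   disables noise.
#' @param seed integer for reproducible noise; `NULL` uses (and advances) the
#'   global RNG stream.
#' @param role `"muscle"` or `"phantom"`.
#' @return a time-domain [Spectrum-class]; identical inputs and seed give a
#'   bit-identical result.
#' @examples
#' acq <- defaultConfig()$acquisition
#' fid <- simulateFID(list(PeakSpec(8.0, linewidthFwhm = 10)), 5,
#'                    VoxelGeometry(40, 12, 28), acq, noiseSd = 0)
#' nPoints(fid)
#' @export
simulateFID <- function(peaks, concentrations, geometry, acq, noiseSd = 0,
                        seed = NULL, role = "muscle") {
  if (inherits(peaks, "PeakSpec")) peaks <- list(peaks)
  if (!is.list(peaks) || !all(vapply(peaks, inherits, logical(1), "PeakSpec")))
    stop("'peaks' must be a list of PeakSpec objects")
  if (length(peaks) != length(concentrations))
    stop("'concentrations' must have one value per peak")
  if (length(noiseSd) != 1L || is.na(noiseSd) || noiseSd < 0)
    stop("'noiseSd' must be a single non-negative number")
  acq <- .checkAcq(acq)

  n <- as.integer(acq$n_points)
  bw <- acq$bandwidth_hz
  f0 <- acq$transmitter_frequency_mhz
  refPpm <- acq$reference_ppm
  nAvg <- as.integer(acq$n_averages)
  tt <- (seq_len(n) - 1L) / bw
  vol <- volume(geometry)

  sig <- complex(real = numeric(n), imaginary = numeric(n))
  for (k in seq_along(peaks)) {
    p <- peaks[[k]]
    df <- (p@center - refPpm) * f0
    if (abs(df) > bw / 2)
      stop(sprintf("peak at %.3f ppm falls outside the spectral bandwidth",
                   p@center))
    # time amplitude = 2 * target absorption area (one-sided decay halves
    # the frequency-domain integral of the real part)
    a <- 2 * p@amplitude * concentrations[k] * vol * nAvg
    env <- switch(p@lineshape,
      lorentzian = exp(-pi * p@linewidthFwhm * tt),
      gaussian   = exp(-(pi * p@linewidthFwhm * tt)^2 / (4 * log(2))),
      stop("unknown lineshape: ", p@lineshape))
    sig <- sig + a * env * exp(2i * pi * df * tt)
  }

  if (noiseSd > 0) {
    sig <- sig + withSeed(seed, {
      sdTot <- noiseSd * sqrt(nAvg)
      complex(real = stats::rnorm(n, 0, sdTot),
              imaginary = stats::rnorm(n, 0, sdTot))
    })
  }

  Spectrum(sig, bandwidth = bw, transmitterFrequency = f0,
           referencePpm = refPpm, echoTime = acq$echo_time_ms,
           repetitionTime = acq$repetition_time_ms, nAverages = nAvg,
           role = role, domain = "time", geometry = geometry)
}

#' Analytic peak area targeted by the simulator
#'
#' The noiseless absorption-mode area that [simulateFID()] produces for one
#' peak; the oracle used when checking the fitted area of [fitPeak()].
#'
#' @param peak a [PeakSpec-class].
#' @param concentration mM.
#' @param geometry [VoxelGeometry-class].
#' @param acq acquisition constant list (only `n_averages` is used).
#' @return area in signal units.
#' @export
truePeakArea <- function(peak, concentration, geometry, acq) {
  peak@amplitude * concentration * volume(geometry) * as.integer(acq$n_averages)
}

.checkAcq <- function(acq) {
  need <- c("repetition_time_ms", "echo_time_ms", "n_points", "bandwidth_hz",
            "n_averages", "transmitter_frequency_mhz", "reference_ppm")
  miss <- setdiff(need, names(acq))
  if (length(miss))
    stop("acquisition constants missing: ", paste(miss, collapse = ", "))
  acq
}

# Polarization normalizer for the Curie 1/T signal dependence; any constant
# cancels in the muscle/phantom ratio.
.curieRefK <- 295.15

# Combined signal attenuation applied by simulateMeasurementPair: T1
# saturation, T2 decay and Curie-law 1/T polarization.
.relaxAttenuation <- function(trMs, teMs, t1Ms, t2Ms, tempK) {
  (1 - exp(-trMs / t1Ms)) * exp(-teMs / t2Ms) * (.curieRefK / tempK)
}

#' Simulate a matched muscle + phantom acquisition
#'
#' Synthesizes the two spectra one quantification needs: the muscle voxel at
#' a known true carnosine concentration and the external reference phantom
#' at its configured concentration (20 mM by default). Both carnosine
#' imidazole resonances (~7.0 and ~8.0 ppm) and a partially suppressed
#' residual water line are simulated, with the T1 saturation, T2 decay and
#' Curie-law temperature attenuation of each compartment folded into the
#' peak amplitudes — exactly the factors the quantification formula corrects
#' for, so a noiseless round trip recovers the truth.
#'
#' @param trueConc true muscle carnosine concentration, mM (> 0).
#' @param config full configuration list (see [defaultConfig()]); must
#'   contain a `relaxation` block.
#' @param seed integer seed for the noise; `NULL` uses the global stream.
#' @param noiseSd per-average FID noise SD; `NULL` takes
#'   `config$noise$fid_noise_sd`, 0 disables noise.
#' @return `list(muscle = Spectrum, phantom = Spectrum)`.
#' @examples
#' pair <- simulateMeasurementPair(4.94, defaultConfig(), seed = 1,
#'                                 noiseSd = 0)
#' spectrumRole(pair$phantom)
#' @export
simulateMeasurementPair <- function(trueConc, config, seed = NULL,
                                    noiseSd = NULL) {
  if (length(trueConc) != 1L || is.na(trueConc) || trueConc <= 0)
    stop("'trueConc' must be a single positive concentration (mM)")
  if (is.null(config$relaxation))
    stop("config missing relaxation block")
  if (is.null(noiseSd)) noiseSd <- config$noise$fid_noise_sd
  acq <- .acqFromConfig(config)
  pk <- config$peaks
  tmp <- config$temperatures

  withSeed(seed, {
    build <- function(role, conc, fwhm, t1, t2, tempK, geomDims) {
      att <- .relaxAttenuation(acq$repetition_time_ms, acq$echo_time_ms,
                               t1, t2, tempK)
      attW <- .relaxAttenuation(acq$repetition_time_ms, acq$echo_time_ms,
                                t1, t2, tempK)
      peaks <- list(
        PeakSpec(pk$carnosine_c2_ppm, amplitude = att,
                 linewidthFwhm = fwhm),
        PeakSpec(pk$carnosine_c4_ppm, amplitude = att,
                 linewidthFwhm = fwhm),
        PeakSpec(pk$water_ppm, amplitude = attW,
                 linewidthFwhm = pk$water_fwhm_hz))
      concs <- c(conc, conc,
                 pk$water_equivalent_mm * pk$water_suppression_factor)
      simulateFID(peaks, concs, .voxelFromConfig(geomDims), acq,
                  noiseSd = noiseSd, seed = NULL, role = role)
    }
    muscle <- build("muscle", trueConc, pk$carnosine_fwhm_muscle_hz,
                    config$relaxation$muscle$t1_ms,
                    config$relaxation$muscle$t2_ms,
                    tmp$muscle_k, config$geometry$muscle_voxel_mm)
    phantom <- build("phantom", config$phantom$concentration_mm,
                     pk$carnosine_fwhm_phantom_hz,
                     config$relaxation$phantom$t1_ms,
                     config$relaxation$phantom$t2_ms,
                     tmp$phantom_k, config$geometry$phantom_voxel_mm)
    list(muscle = muscle, phantom = phantom)
  })
}
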