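test_that("preprocessing honors its length and identity contracts", {
  fid <- lorentzFid()
  expect_identical(nPoints(preprocess(fid, 0, 2L)), 2048L)
  expect_error(preprocess(fid, 0, 0L), "zeroFillFactor")
  # identity settings reproduce the plain (trapezoid-corrected, scaled,
  # frequency-ordered) transform of the FID
  sp <- preprocess(fid, 0, 1L)
  s <- samples(fid)
  s[1] <- s[1] / 2
  f <- stats::fft(s) / bandwidth(fid)
  n <- length(f); m <- ceiling(n / 2)
  expect_equal(samples(sp), c(f[(m + 1):n], f[1:m]), tolerance = 1e-12)
  # apodization/zero-fill are time-domain operations
  expect_error(preprocess(sp, 5, 1L), "time-domain")
})

test_that("exponential apodization adds its width to a Lorentzian line", {
  fid <- lorentzFid(fwhm = 10)
  fit <- fitPeak(preprocess(fid, 5, 2L), c(7.4, 8.6))
  expect_lt(abs(linewidth(fit) - 15) / 15, 0.02)
})

test_that("water referencing removes a known injected offset", {
  # water synthesized off-reference at 4.80 ppm
  fid <- lorentzFid(ppm = 4.80, fwhm = 25.7)
  ref <- referenceToWater(fid)
  expect_equal(referencePpm(ref) - referencePpm(fid), -0.10,
               tolerance = 1e-3)
  # already-referenced water: zero shift
  fid0 <- lorentzFid(ppm = 4.70, fwhm = 25.7)
  expect_equal(referencePpm(referenceToWater(fid0)), referencePpm(fid0),
               tolerance = 1e-3)
  # noise-only spectrum has no water to find
  noise <- simulateFID(list(), numeric(0), stdGeom(), stdAcq(),
                       noiseSd = 1e5, seed = 2)
  expect_error(referenceToWater(noise), "water not found")
})

test_that("water linewidth estimator recovers the true FWHM", {
  # the protocol-typical 25.7 Hz line, no noise
  fid <- lorentzFid(ppm = 4.70, fwhm = 25.7)
  expect_lt(abs(estimateWaterLinewidth(fid) - 25.7), 0.5)
  # parameter sweep over the realistic shim range, both lineshapes
  for (g in c(5, 12, 25.7, 40, 60)) {
    fidL <- lorentzFid(ppm = 4.70, fwhm = g)
    expect_lt(abs(estimateWaterLinewidth(fidL) - g) / g, 0.02)
  }
  for (g in c(10, 25.7, 50)) {
    fidG <- lorentzFid(ppm = 4.70, fwhm = g, lineshape = "gaussian")
    expect_lt(abs(estimateWaterLinewidth(fidG) - g) / g, 0.02)
  }
})

test_that("fitPeak recovers noiseless areas to a fraction of a percent", {
  truth <- truePeakArea(PeakSpec(8.0, 1, 12), 5, stdGeom(), stdAcq())
  fit <- fitPeak(preprocess(lorentzFid(), 0, 2L), c(7.4, 8.6))
  expect_true(converged(fit))
  expect_lt(abs(peakArea(fit) / truth - 1), 0.001)
  expect_equal(peakCenter(fit), 8.0, tolerance = 1e-3)
  # gaussian lineshape path
  fidG <- lorentzFid(lineshape = "gaussian")
  fitG <- fitPeak(preprocess(fidG, 0, 2L), c(7.4, 8.6),
                  lineshape = "gaussian")
  expect_lt(abs(peakArea(fitG) / truth - 1), 0.001)
  expect_equal(linewidth(fitG), 12, tolerance = 0.1)
})

test_that("the C2-H area survives overlap with the C4-H resonance", {
  fid <- simulateFID(list(PeakSpec(8.0, 1, 12), PeakSpec(7.0, 1, 12)),
                     c(5, 5), stdGeom(), stdAcq(), 0)
  truth <- truePeakArea(PeakSpec(8.0, 1, 12), 5, stdGeom(), stdAcq())
  fit <- fitPeak(preprocess(fid, 0, 2L), c(7.4, 8.6))
  expect_lt(abs(peakArea(fit) / truth - 1), 0.02)
})

test_that("a pure-noise window yields an honest null result", {
  noise <- simulateFID(list(), numeric(0), stdGeom(), stdAcq(),
                       noiseSd = 1e5, seed = 4)
  fit <- fitPeak(preprocess(noise, 0, 2L), c(7.4, 8.6))
  typical <- truePeakArea(PeakSpec(8.0, 0.5, 12), 5, stdGeom(), stdAcq())
  expect_true(!converged(fit) || peakArea(fit) < 0.1 * typical)
})

test_that("fitPeak rejects invalid windows", {
  sp <- preprocess(lorentzFid(), 0, 2L)
  expect_error(fitPeak(sp, c(8.0, 8.0)), "non-empty")
  expect_error(fitPeak(sp, c(30, 40)), "outside the spectral range")
  expect_error(fitPeak(sp, c(8.000, 8.002)), "fewer than 8")
  expect_error(fitPeak(lorentzFid(), c(7.4, 8.6)), "frequency-domain")
})

test_that("fitted area is invariant to zero-fill on noiseless input", {
  fid <- lorentzFid()
  areas <- vapply(c(1L, 2L, 4L), function(zf)
    peakArea(fitPeak(preprocess(fid, 0, zf), c(7.4, 8.6))), numeric(1))
  expect_lt(max(areas) / min(areas) - 1, 0.005)
})

test_that("linewidth estimator and peak fit agree on noiseless Lorentzians", {
  for (g in c(10, 25.7)) {
    fid <- lorentzFid(ppm = 4.70, fwhm = g)
    est <- estimateWaterLinewidth(fid)
    fit <- fitPeak(preprocess(fid, 0, 2L), c(4.3, 5.1))
    expect_lt(abs(est - linewidth(fit)) / linewidth(fit), 0.05)
  }
})
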