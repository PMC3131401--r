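test_that("null signal and degenerate inputs behave exactly", {
  fid <- simulateFID(list(PeakSpec(8.0, amplitude = 0)), 5, stdGeom(),
                     stdAcq(), noiseSd = 0)
  expect_true(all(samples(fid) == 0 + 0i))
  expect_error(simulateFID(list(PeakSpec(8.0)), 5, stdGeom(), stdAcq(),
                           noiseSd = -1), "noiseSd")
  # 20 ppm is (20 - 4.7) * 123.2 Hz = far outside the 1200 Hz bandwidth
  expect_error(simulateFID(list(PeakSpec(20)), 5, stdGeom(), stdAcq(), 0),
               "outside the spectral bandwidth")
  acq <- stdAcq(); acq$bandwidth_hz <- NULL
  expect_error(simulateFID(list(PeakSpec(8)), 5, stdGeom(), acq, 0),
               "bandwidth_hz")
})

test_that("FID energy equals spectral energy (Parseval, direct-sum oracle)", {
  fid <- lorentzFid(conc = 5, fwhm = 12)
  s <- samples(fid)
  eTime <- sum(Mod(s)^2)
  eFreq <- sum(Mod(stats::fft(s))^2) / length(s)
  expect_equal(eFreq, eTime, tolerance = 1e-12)
})

test_that("identical seed and inputs give bit-identical spectra", {
  a <- lorentzFid(noiseSd = 1e5, seed = 42)
  b <- lorentzFid(noiseSd = 1e5, seed = 42)
  expect_identical(samples(a), samples(b))
  c <- lorentzFid(noiseSd = 1e5, seed = 43)
  expect_false(identical(samples(a), samples(c)))
  p1 <- simulateMeasurementPair(4.94, stdConfig(), seed = 7)
  p2 <- simulateMeasurementPair(4.94, stdConfig(), seed = 7)
  expect_identical(samples(p1$muscle), samples(p2$muscle))
  expect_identical(samples(p1$phantom), samples(p2$phantom))
})

test_that("noiseless peak area is exactly linear in concentration", {
  concs <- seq(1, 10, length.out = 10)
  areas <- vapply(concs, function(cc) {
    fit <- fitPeak(preprocess(lorentzFid(conc = cc), 0, 2L), c(7.4, 8.6))
    peakArea(fit)
  }, numeric(1))
  fit <- stats::lm(areas ~ concs)
  expect_gt(summary(fit)$r.squared, 0.999)
  # slope equals the analytic area per mM
  perMM <- truePeakArea(PeakSpec(8.0, 1, 12), 1, stdGeom(), stdAcq())
  expect_equal(unname(stats::coef(fit)[2]), perMM, tolerance = 5e-3)
})

test_that("measurement pair carries role, geometry and exact phantom truth", {
  cfg <- stdConfig()
  pair <- simulateMeasurementPair(4.94, cfg, noiseSd = 0)
  expect_identical(spectrumRole(pair$muscle), "muscle")
  expect_identical(spectrumRole(pair$phantom), "phantom")
  expect_equal(volume(pair$muscle), prod(unlist(cfg$geometry$muscle_voxel_mm)))
  expect_equal(volume(pair$phantom),
               prod(unlist(cfg$geometry$phantom_voxel_mm)))
  cfgNoRelax <- cfg; cfgNoRelax$relaxation <- NULL
  expect_error(simulateMeasurementPair(4.94, cfgNoRelax, noiseSd = 0),
               "relaxation")
  # the phantom quantified against itself is the identity: exactly 20 mM
  # up to fit numerics
  cfgSelf <- cfg
  cfgSelf$relaxation$muscle <- cfg$relaxation$phantom
  cfgSelf$temperatures$muscle_k <- cfg$temperatures$phantom_k
  cfgSelf$geometry$muscle_voxel_mm <- cfg$geometry$phantom_voxel_mm
  res <- quantifyPair(pair$phantom, pair$phantom, cfgSelf)
  expect_equal(res$concentration_mM, 20, tolerance = 1e-9)
})

test_that("cohort cells reproduce configured means and plausible ranges", {
  cfg <- stdConfig()
  # large-n single cell converges to the configured mean at the SD/sqrt(n)
  # rate
  cfg$cohort$cells <- list(list(sex = "male", group = "control",
                                category = "control", n = 4000,
                                mean_mm = 4.94, sd_mm = 1.43,
                                both_legs = FALSE, discipline = "untrained"))
  coh <- simulateCohort(cfg, seed = 8)
  se <- 1.43 / sqrt(4000)
  expect_lt(abs(mean(coh$carnosine_mean_mM) - 4.94), 4 * se)
  expect_lt(abs(stats::sd(coh$carnosine_mean_mM) - 1.43), 0.1)
  # concentrations stay positive and the bulk sits inside the range
  # observed in male controls (1.68-7.85 mM)
  expect_true(all(coh$carnosine_mean_mM > 0))
  q <- stats::quantile(coh$carnosine_mean_mM, c(0.005, 0.995))
  expect_gt(q[[1]], 0.8)
  expect_lt(q[[2]], 10)
  # a study-sized draw (n = 47) brackets the printed extremes
  sub <- coh$carnosine_mean_mM[1:47]
  expect_lt(min(sub), 3.5)
  expect_gt(max(sub), 6.5)
})

test_that("zero measurement CV makes the two legs identical", {
  cfg <- stdConfig()
  cfg$cohort$measurement_cv <- 0
  coh <- simulateCohort(cfg, seed = 3)
  both <- !is.na(coh$carnosine_right_mM)
  expect_true(any(both))
  expect_equal(coh$carnosine_left_mM[both], coh$carnosine_right_mM[both])
  expect_equal(coh$carnosine_left_mM[both], coh$carnosine_true_mM[both])
})

test_that("seeded cohorts are reproducible and errors are raised early", {
  expect_identical(simulateCohort(stdConfig(), seed = 1),
                   simulateCohort(stdConfig(), seed = 1))
  cfg <- stdConfig(); cfg$cohort$cells <- list()
  expect_error(simulateCohort(cfg), "empty cohort")
})

test_that("noise-free runner panel evaluates the truth sigmoid exactly", {
  cfg <- stdConfig()
  truth <- SigmoidModel(cfg$sigmoid$top, cfg$sigmoid$bottom,
                        cfg$sigmoid$d50_m, cfg$sigmoid$hill)
  rp <- simulateRunnerPanel(cfg, distances = c(100, 42195), zNoiseSd = 0)
  expect_equal(rp$z_score, predictZ(truth, c(100, 42195)))
  # logistic symmetry at the midpoint
  rp50 <- simulateRunnerPanel(cfg, distances = cfg$sigmoid$d50_m,
                              zNoiseSd = 0)
  expect_equal(rp50$z_score, (cfg$sigmoid$top + cfg$sigmoid$bottom) / 2)
  expect_error(simulateRunnerPanel(cfg, distances = c(100, -5)),
               "distances must be > 0")
})
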