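test_that("Pearson correlation honors exact and degenerate cases", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -2 * x + 1)$r, -1)
  expect_error(pearsonCorrelation(x, rep(2, 5)), "zero variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "at least 3")
})

test_that("t-transform p approximates the permutation p at finite n", {
  # the two p-values are different estimands (unconditional normal-theory
  # vs conditional permutation); their difference shrinks as O(1/n), so
  # the tolerance combines Monte-Carlo error with a finite-sample term
  set.seed(101)
  for (n in c(5, 12, 30)) {
    x <- stats::rnorm(n)
    y <- 0.6 * x + 0.8 * stats::rnorm(n)
    pc <- pearsonCorrelation(x, y)
    B <- 20000
    perm <- replicate(B, abs(stats::cor(x, sample(y))))
    pPerm <- mean(perm >= abs(pc$r))
    mcsd <- sqrt(pPerm * (1 - pPerm) / B)
    expect_lt(abs(pc$p_value - pPerm), max(3 * mcsd, 0.6 / n))
  }
})

test_that("calibration fit matches the closed-form normal equations", {
  # frozen 5-point hand oracle
  x <- c(30, 38, 45, 52, 60)
  y <- c(4.1, 4.6, 4.8, 5.3, 5.6)
  m <- fitCalibration(x, y)
  expect_equal(m@slope, 0.05, tolerance = 1e-12)
  expect_equal(m@intercept, 2.63, tolerance = 1e-12)
  expect_equal(m@residualSd, 0.0774596669241483, tolerance = 1e-12)
  expect_equal(m@r, 0.993494690619021, tolerance = 1e-12)
  expect_equal(m@pValue, 0.000629233091681404, tolerance = 1e-9)
  # exactly collinear points interpolate with zero residual
  mc <- fitCalibration(c(30, 40, 50, 60), 2 + 0.04 * c(30, 40, 50, 60))
  expect_equal(mc@slope, 0.04)
  expect_equal(mc@intercept, 2)
  expect_equal(mc@residualSd, 0)
})

test_that("synthetic calibration sets center on the configured correlation", {
  cfg <- stdConfig()
  set.seed(12)
  rs <- replicate(300, {
    d <- simulateCalibrationSet(cfg)
    fitCalibration(d$ft_area_pct, d$carnosine_mM)@r
  })
  # mean recovered r within the Monte-Carlo CI of the biopsy-study value
  expect_lt(abs(mean(rs) - 0.714), 3 * stats::sd(rs) / sqrt(length(rs)) +
              0.02)
})

test_that("inverse regression honors the OLS centroid and exact models", {
  x <- c(30, 38, 45, 52, 60)
  y <- c(4.1, 4.6, 4.8, 5.3, 5.6)
  m <- fitCalibration(x, y)
  # carnosine at the response mean maps to the predictor mean
  p <- predictFtArea(m, m@yMean)
  expect_equal(p$estimate, m@xMean)
  # noiseless collinear calibration gives zero-width intervals
  mc <- fitCalibration(c(30, 40, 50, 60), 2 + 0.04 * c(30, 40, 50, 60))
  pc <- predictFtArea(mc, 3.8)
  expect_equal(pc$lower, pc$estimate)
  expect_equal(pc$upper, pc$estimate)
  zero <- fitCalibration(c(30, 40, 50, 60), 2 + 0.04 * c(30, 40, 50, 60))
  zero@slope <- 0
  expect_error(predictFtArea(zero, 4), "uninformative")
  # estimates outside the physical range are clamped and flagged
  expect_warning(out <- predictFtArea(m, 30), "clamped")
  expect_equal(out$estimate, 100)
  expect_true(out$clamped)
})

test_that("inverse regression at the calibration points has mean-zero residuals", {
  set.seed(6)
  d <- simulateCalibrationSet(stdConfig(), n = 30)
  m <- fitCalibration(d$ft_area_pct, d$carnosine_mM)
  est <- suppressWarnings(predictFtArea(m, d$carnosine_mM)$estimate)
  resid <- est - d$ft_area_pct
  expect_lt(abs(mean(resid)), 2 * stats::sd(resid) / sqrt(nrow(d)) + 1e-8)
})

test_that("axis mapping is linear, monotone and self-inverse", {
  x <- c(30, 38, 45, 52, 60)
  m <- fitCalibration(x, 3.4 + 0.034 * x)
  ticks <- c(m@yMean - m@slope * 10, m@yMean, m@yMean + m@slope * 10)
  expect_equal(carnosineAxisToFtAxis(m, ticks),
               c(m@xMean - 10, m@xMean, m@xMean + 10))
  mm <- seq(3, 7, by = 0.5)
  pct <- carnosineAxisToFtAxis(m, mm)
  expect_true(all(diff(pct) > 0))
  # percent -> mM -> percent round trip
  back <- carnosineAxisToFtAxis(m, m@intercept + m@slope * pct)
  expect_equal(back, pct, tolerance = 1e-12)
})
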