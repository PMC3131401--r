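test_that("Z-scores follow the reference convention", {
  ref <- ReferenceStats("male", 4.94, 1.43, 47)
  expect_equal(zScore(4.94, ref), 0)
  expect_equal(zScore(4.94 + 1.43, ref), 1)
  expect_equal(zScore(6.37, ref), 1)     # printed reference mean + SD
  # affine equivariance: shifting values and reference together
  ref2 <- ReferenceStats("male", 4.94 + 2, 1.43, 47)
  v <- c(3.1, 4.94, 7.2)
  expect_equal(zScore(v + 2, ref2), zScore(v, ref))
})

test_that("reference stats derive per sex from the control rows", {
  coh <- simulateCohort(stdConfig(), seed = 2)
  refs <- referenceStatsFromCohort(coh)
  expect_named(refs, c("female", "male"))
  expect_identical(refs$male@n, 47L)
  ctrlM <- coh$carnosine_mean_mM[coh$group == "control" &
                                 coh$sex == "male"]
  expect_equal(refs$male@mean, mean(ctrlM))
  z <- addZScores(coh, refs)
  expect_equal(mean(z$z_score[z$group == "control" & z$sex == "male"]), 0,
               tolerance = 1e-12)
})

test_that("summary t-test reproduces the published group contrasts", {
  # former sprint vs endurance athletes: printed p = 0.012
  ex <- summaryTTest(7, 5.11, 1.07, 7, 3.61, 0.81)
  expect_equal(round(ex$p_value, 3), 0.012)
  expect_identical(ex$df, 12)
  # young talents: printed p = 0.019 from 2-decimal summaries
  tal <- summaryTTest(7, 6.88, 1.83, 8, 4.90, 0.93)
  expect_gte(tal$p_value, 0.017)
  expect_lte(tal$p_value, 0.021)
  # identical summaries: exact null
  id <- summaryTTest(5, 4, 1, 5, 4, 1)
  expect_equal(id$t, 0)
  expect_equal(id$p_value, 1)
  expect_error(summaryTTest(1, 4, 1, 5, 4, 1), ">= 2")
})

test_that("pooled summary t-test equals the raw-sample t-test exactly", {
  set.seed(14)
  for (i in 1:5) {
    a <- stats::rnorm(7, 5, 1.2)
    b <- stats::rnorm(9, 4, 0.8)
    st <- summaryTTest(7, mean(a), stats::sd(a), 9, mean(b), stats::sd(b))
    rt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(st$t, unname(rt$statistic), tolerance = 1e-12)
    expect_equal(st$p_value, rt$p.value, tolerance = 1e-12)
    sw <- summaryTTest(7, mean(a), stats::sd(a), 9, mean(b), stats::sd(b),
                       variant = "welch")
    rw <- stats::t.test(a, b)
    expect_equal(sw$p_value, rw$p.value, tolerance = 1e-12)
    expect_equal(sw$df, unname(rw$parameter), tolerance = 1e-12)
  }
})

test_that("group summaries use interpolated quartiles and handle n = 1", {
  coh <- data.frame(subject_id = letters[1:6], sex = "male",
                    group = c(rep("elite", 5), "control"),
                    category = c(rep("explosive", 5), "control"),
                    carnosine_mean_mM = c(3.2, 4.1, 4.8, 5.0, 6.4, 4.4))
  s <- groupSummaries(coh, c("group", "category"))
  ex <- s[s$category == "explosive", ]
  # hand-computed type-7 quartiles of (3.2, 4.1, 4.8, 5.0, 6.4)
  expect_equal(ex$q1, 4.1)
  expect_equal(ex$median, 4.8)
  expect_equal(ex$q3, 5.0)
  one <- s[s$category == "control", ]
  expect_equal(one$mean, 4.4)
  expect_equal(one$median, 4.4)
  expect_true(is.na(one$sd))
  expect_error(groupSummaries(coh, "flavour"), "unknown column")
})

test_that("percent differences and fold changes match printed arithmetic", {
  expect_equal(percentDifference(6.58, 4.94), 33.1984, tolerance = 1e-4)
  expect_equal(percentDifference(3.75, 4.94), -24.0891, tolerance = 1e-4)
  expect_equal(percentDifference(5, 5), 0)
  expect_error(percentDifference(5, 0), "> 0")
  expect_equal(foldChange(6.58, 3.75), 6.58 / 3.75)
  expect_equal(foldChange(4, 4), 1)
  expect_error(foldChange(4, 0), "> 0")
})

test_that("sprint vs endurance subgroup ratio tracks the generator truth", {
  cfg <- stdConfig()
  set.seed(21)
  rp <- simulateRunnerPanel(cfg, distances = rep(c(100, 200, 400, 42195,
                                                   10000, 3000), each = 20))
  sprint <- rp$carnosine_mean_mM[rp$best_distance_m <= 400]
  endur <- rp$carnosine_mean_mM[rp$best_distance_m >= 3000]
  truthTop <- 4.94 + cfg$sigmoid$top * 1.43
  truthBot <- 4.94 + cfg$sigmoid$bottom * 1.43
  fc <- foldChange(mean(sprint), mean(endur))
  expect_lt(abs(fc - truthTop / truthBot), 0.15)
})

test_that("sigmoid fitting recovers exact and perturbed models", {
  truth <- SigmoidModel(1.15, -0.85, 1000, 3)
  d <- c(100, 200, 400, 800, 1500, 3000, 10000, 42195)
  fit <- fitSigmoid(d, predictZ(truth, d))
  expect_true(converged(fit) || fit@rSquared > 1 - 1e-10)
  expect_equal(fit@top, 1.15, tolerance = 1e-6)
  expect_equal(fit@bottom, -0.85, tolerance = 1e-6)
  expect_equal(fit@d50, 1000, tolerance = 1e-3)
  expect_equal(fit@hill, 3, tolerance = 1e-5)
  expect_equal(fit@rSquared, 1, tolerance = 1e-10)
  expect_error(fitSigmoid(d[1:4], predictZ(truth, d[1:4])), "at least 5")
  expect_error(fitSigmoid(c(d, -1), c(predictZ(truth, d), 0)), "> 0")
})

test_that("sigmoid fit is invariant to point order and distance units", {
  set.seed(33)
  rp <- simulateRunnerPanel(stdConfig())
  f1 <- fitSigmoid(rp$best_distance_m, rp$z_score)
  shuffle <- sample(nrow(rp))
  f2 <- fitSigmoid(rp$best_distance_m[shuffle], rp$z_score[shuffle])
  expect_equal(f1@d50, f2@d50, tolerance = 1e-6)
  fkm <- fitSigmoid(rp$best_distance_m / 1000, rp$z_score)
  expect_equal(fkm@d50 * 1000, f1@d50, tolerance = 1e-4)
  expect_equal(fkm@hill, f1@hill, tolerance = 1e-4)
})

test_that("sigmoid predictions follow the asymptotes and monotonicity", {
  m <- SigmoidModel(1.15, -0.85, 1000, 3)
  expect_equal(predictZ(m, 1e-6), 1.15, tolerance = 1e-6)
  expect_equal(predictZ(m, 1e9), -0.85, tolerance = 1e-6)
  expect_equal(predictZ(m, 1000), (1.15 - 0.85) / 2)
  z <- predictZ(m, c(100, 400, 800, 1500, 10000, 42195))
  expect_true(all(diff(z) < 0))
  expect_error(predictZ(m, 0), "> 0")
})
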