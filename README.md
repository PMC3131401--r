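# carnotype

Non-invasive estimation of human muscle fiber-type composition from
single-voxel ¹H-MRS measurements of muscle carnosine.

## The problem

Skeletal muscle fibers come in two main categories — slow-twitch (type-I)
and fast-twitch (type-II) — and the balance between them is a strong
determinant of athletic aptitude across running distances, as well as a
marker in several muscle-wasting conditions. The gold-standard measurement,
needle biopsy with immunohistochemical fiber typing, is invasive and samples
a tiny, poorly representative fraction of the muscle. The dipeptide
carnosine concentrates roughly twice as high in fast-twitch as in
slow-twitch fibers and is a stable individual characteristic, so its
concentration — measurable *in vivo* by proton magnetic resonance
spectroscopy (¹H-MRS) from a 10–15 ml voxel — serves as a non-invasive proxy
for percent type-II fiber area.

`carnotype` implements that measurement chain end to end, with a synthetic
data generator that provides known ground truth at every stage:

1. **Simulation** (`simulateFID()`, `simulateMeasurementPair()`,
   `simulateCohort()`, `simulateRunnerPanel()`) — PRESS free-induction
   decays (TR 2000 ms, TE 30 ms, 1024 points, 1200 Hz bandwidth, 128
   averages) with Lorentzian/Gaussian resonances, residual water, seeded
   noise; cohorts with configurable per-cell means/SDs and a FT:ST
   carnosine ratio of 2.
2. **Spectral analysis** (`preprocess()`, `referenceToWater()`,
   `estimateWaterLinewidth()`, `fitPeak()`) — apodization, zero filling,
   Fourier transform, water referencing, and model-based peak fitting
   (complex-domain Lorentzian with free phase, analytic area).
3. **Absolute quantification** (`absoluteConcentration()` and friends) —
   the external-reference formula

   C_m = C_r · (S_m/S_r) · (V_r/V_m) · (C_T1m·C_T2m)/(C_T1r·C_T2r) · (T_m/T_r)

   with saturation factors C_T1 = 1/(1 − e^(−TR/T1)), decay factors
   C_T2 = e^(TE/T2), voxel volumes V, and the Curie-law temperature ratio;
   the reference phantom holds 20 mM carnosine.
4. **Fiber-type calibration** (`fitCalibration()`, `predictFtArea()`) —
   OLS of carnosine on biopsy-determined percent type-II area, with
   inverse-regression (Fieller) prediction intervals for new subjects.
5. **Cohort analytics** (`zScore()`, `summaryTTest()`, `groupSummaries()`,
   `percentDifference()`, `foldChange()`, `fitSigmoid()`, `predictZ()`) —
   sex-stratified Z-scores, pooled/Welch t-tests from printed summaries,
   and the four-parameter logistic
   z(d) = bottom + (top − bottom)/(1 + (d/d50)^hill)
   of Z-score versus log₁₀ running distance, whose midpoint d50 falls near
   1000 m for elite runners.

All tunable constants (relaxation times, temperatures, noise level, peak
model, cohort cells) live in a YAML configuration
(`inst/extdata/default_config.yaml`, merged by `readConfig()`), not in code.

## Worked example

Simulate one muscle/phantom acquisition at a true 5.6 mM, quantify it, and
map the result to fiber type:

```r
library(carnotype)
cfg  <- defaultConfig()
pair <- simulateMeasurementPair(5.6, cfg, seed = 42)
res  <- quantifyPair(pair$muscle, pair$phantom, cfg)
res$factors
#   signal_ratio       0.449074
#   volume_ratio       0.595238
#   c_t1m              1.27342
#   c_t2m              1.45499
#   c_t1r              1.86348
#   c_t2r              1.06184
#   temperature_ratio  1.05082
res$concentration_mM
# 5.2604
```

The audit shows every term of the formula: the muscle-to-phantom signal
ratio, the volume ratio, the four relaxation corrections and the
temperature ratio. The recovered 5.26 mM differs from the 5.6 mM truth by a
single-measurement noise error (test–retest CV of the simulated protocol is
about 9 %; averaging both legs, as done for athletes, halves the variance).

Calibrate against biopsy pairs and estimate fiber type:

```r
m <- fitCalibration(ftAreaPct = c(30, 38, 45, 52, 60),
                    carnosineMM = c(4.1, 4.6, 4.8, 5.3, 5.6))
m
# CalibrationModel: carnosine (mM) ~ percent type-II area
#   slope 0.05 mM/% | intercept 2.63 mM | n = 5
#   r = 0.993 | p = 0.0006292 | residual SD 0.07746 mM
predictFtArea(m, res$concentration_mM)
#   estimate lower upper clamped
#      52.61 47.19 58.73   FALSE
zScore(res$concentration_mM, ReferenceStats("male", 4.94, 1.43, 47))
# 0.224
```

So this simulated subject sits an estimated 52.6 % type-II area (95 %
prediction interval 47–59 %), 0.22 reference SDs above the male control
mean — a mildly fast-twitch profile.

A command-line wrapper covers the same pipelines
(`inst/scripts/carnotype <simulate|quantify|calibrate|cohort|sigmoid>`).

## Documentation

The methods vignette (`vignettes/carnosine-mrs.Rmd`) describes the signal
model, the quantification formula and its assumptions, every default the
generator uses and why, the numerical choices in the fitting routines, and
the known limitations of the synthetic data.
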