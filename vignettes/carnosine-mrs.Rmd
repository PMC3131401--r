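---
title: "Muscle carnosine ¹H-MRS: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle carnosine ¹H-MRS: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnotype)
```

# The measurement and its model

Muscle carnosine (β-alanyl-L-histidine) concentrates about twice as high in
fast-twitch (type-II) as in slow-twitch (type-I) fibers, and its imidazole
protons resonate at ~7.0 (C4-H) and ~8.0 ppm (C2-H), well clear of the water
and lipid regions. A single-voxel PRESS acquisition on the gastrocnemius
therefore yields a carnosine signal whose absolute concentration tracks the
muscle's fiber-type composition.

`carnotype` models one acquisition as a complex free induction decay

$$s(t) \;=\; \sum_k A_k\, g_k(t)\, e^{2\pi i \Delta f_k t} \;+\;
\varepsilon(t),$$

where $\Delta f_k$ is the offset of resonance $k$ from the transmitter
(ppm offset × transmitter frequency in MHz), $g_k$ is an exponential
(Lorentzian line) or Gaussian envelope parameterized by the full width at
half maximum (FWHM), and $\varepsilon$ is complex white noise. The time
amplitude $A_k$ is scaled so that the analytic absorption-mode area of peak
$k$ equals `amplitude × concentration × voxel volume × n_averages` — the
linear-in-concentration property that absolute quantification relies on
(`truePeakArea()` exposes the oracle). Signal grows linearly and noise with
the square root of the number of averages, as for summed acquisitions.

## Absolute quantification

With an external reference phantom of known concentration $C_r$ measured
alongside the subject, the muscle concentration is

$$C_m \;=\; C_r\cdot\frac{S_m}{S_r}\cdot\frac{V_r}{V_m}\cdot
\frac{C_{T1m}\,C_{T2m}}{C_{T1r}\,C_{T2r}}\cdot\frac{T_m}{T_r},$$

with fitted peak areas $S$, voxel volumes $V$, saturation corrections
$C_{T1} = 1/(1-e^{-TR/T1})$, decay corrections $C_{T2} = e^{TE/T2}$, and
absolute temperatures $T$. Two structural choices deserve comment:

* **Arrangement.** The correction factors multiply the muscle signal and
  divide the phantom signal, so that when every muscle parameter equals its
  phantom counterpart and $S_m = S_r$, the formula returns exactly $C_r$.
  This identity is asserted in the test suite and is the defining sanity
  check for any rearrangement a user might configure.
* **Temperature direction.** Equilibrium polarization follows the Curie law
  ($\propto 1/T$), so the warmer muscle is *penalized* relative to the
  room-temperature phantom and the ratio enters as $T_m/T_r > 1$. The
  simulator applies the same $1/T$ attenuation, making the noiseless round
  trip (truth in → truth out within 0.5 %) a joint check of both
  directions.

## Parameters and defaults

All tunables live in `inst/extdata/default_config.yaml`; `readConfig()`
merges a user file over the defaults. The key entries, with units:

| parameter | default | why |
|---|---|---|
| TR, TE | 2000 ms, 30 ms | the PRESS protocol this package emulates |
| points, bandwidth, averages | 1024, 1200 Hz, 128 | same protocol |
| transmitter frequency | 123.2 MHz | proton frequency at 3 T |
| muscle voxel | 40×12×28 mm (13.44 ml) | the protocol's average voxel |
| phantom concentration | 20 mM | the external reference |
| muscle T1/T2 (carnosine) | 1300 / 80 ms | literature-guided; in vivo values at 3 T are not settled, so they are config entries, never buried constants |
| phantom T1/T2 | 2600 / 500 ms | aqueous solutions relax more slowly |
| temperatures | 310.15 / 295.15 K | body vs room temperature |
| carnosine FWHM | 12 Hz muscle, 8 Hz phantom | consistent with a 25.7 Hz water line after shimming |
| water suppression factor | 0.005 | residual water ~1 % of carnosine-region scale; suppression method is a free modeling choice |
| FID noise SD | 1.4e5 per average | calibrated once so 128-average quantification shows a test-retest CV near the method's published repeatability (~9–12 %); see below |

## What the generator emulates — and what it does not

The synthetic cohort draws, per configured (sex × group × category) cell, a
true percent type-II area from a scaled Beta distribution
(Beta($\mu k$, $(1-\mu)k$), $k = 20$; centers 0.45 control, 0.65 explosive,
0.30 endurance, 0.55 mixed — the biopsy literature constrains only the
control range, so the athlete centers are explicit, documented choices), a
true carnosine affine in that area (FT:ST ratio 2), rescaled so the
*reported* cell mean and SD match the configured values in expectation
(the measurement-noise share, halved for bilateral means, is subtracted
from the between-subject spread), and per-leg measurements equal to truth
times mean-one lognormal noise with CV 0.12 — between the published
untrained (11.9 %) and trained (13.2 %) test-retest CVs, and lognormal so
concentrations stay positive. Controls are measured in one leg, athletes in
both, as in the emulated protocol.

The runner panel generates Z-scores from a ground-truth four-parameter
logistic (top 1.15, bottom −0.85, d50 1000 m, hill 3 — asymptotes chosen so
the explosive and endurance cell means map onto them through the male
reference statistics) plus Gaussian noise (SD 0.25 Z), then back-computes
carnosine through the sex-matched reference.

Not emulated: J-coupling evolution and spatial-localization artifacts,
eddy currents, motion, frequency drift, baseline macromolecules, and any
between-session biological drift. Passing tests therefore demonstrate that
the *analysis chain* is unbiased and correctly calibrated under the stated
signal model — not that it is robust to every artifact of real scanner
data.

# Numerical choices

**Preprocessing.** The first FID point is halved before the FFT
(trapezoidal rule), which makes the discrete spectrum a second-order
approximation of the continuous Fourier integral and removes the constant
baseline offset; samples are scaled by the dwell time and reordered to
ascending frequency. Exponential apodization of $a$ Hz adds exactly $a$ Hz
to a Lorentzian FWHM (asserted in the tests); the default is a mild 2 Hz.
Zero filling (default ×2) interpolates without changing areas — fitted
areas are invariant within 0.5 % across factors 1/2/4.

**Water referencing and linewidth.** The water peak is located by magnitude
with parabolic sub-bin refinement; the axis is corrected through the
reference-ppm metadata, leaving samples untouched. The linewidth estimator
rotates the peak to pure absorption using the zero-order phase taken from
its own complex value and interpolates the half-maximum crossings of the
real part. The magnitude profile is deliberately *not* used: for a
Lorentzian its FWHM is √3 times the absorption FWHM, so a magnitude-based
estimate could not reproduce the true width. The absorption route recovers
the exact FWHM for both Lorentzian and Gaussian lines (2 % over 5–60 Hz in
the tests).

**Peak fitting.** `fitPeak()` fits one resonance plus a polynomial baseline
by Levenberg–Marquardt (`minpack.lm::nls.lm`; parameter tolerance 1e-8, up
to 500 iterations) from three linewidth starts (10/25/40 Hz), keeping the
lowest-RMSE solution. For Lorentzians the fit runs in the complex domain —
absorption and dispersion jointly, zero-order phase as a free parameter,
independent per-channel baselines. This choice came out of a bias study:
fitting the real part after a pointwise phase estimate left a noise-induced
area bias of ~2 % at pipeline SNR (the dispersive tail of residual water
corrupts the phase estimate, and the area–width coupling inflates the
mean), whereas the complex fit cuts the bias to well under 1 % and the
variance by ~30 %. Gaussians, whose dispersion has no closed form, keep the
real-part route with an edge-baseline-corrected phase estimate. The default
window, 7.4–8.6 ppm around the C2-H resonance, is wider than the peak
itself because the Lorentzian wings carry a substantial share of the area
information; narrower windows measurably inflated both bias and variance,
while windows reaching past 7.3 ppm pick up the C4-H tail. The C2-H peak is
quantified (not C4-H) because the 7.0 ppm region overlaps residual
aromatic/amide signal in vivo. Baseline order 1 suffices for the complex
fit. Non-convergence is reported honestly through the `converged` flag —
a pure-noise window returns either a non-converged fit or a near-zero area,
never a fabricated peak.

**Noise default.** The per-average FID noise SD is the one generator
parameter not fixed by the emulated protocol. It was calibrated once, by a
repeat-measurement experiment at the reference concentration, so that the
full pipeline's test-retest CV lands inside the 8–16 % band that brackets
the method's published repeatability, and then frozen; at that level the
pipeline's mean bias is below 1 %.

**Calibration and inverse regression.** The biopsy calibration is OLS of
carnosine on percent type-II area — the direction the data are plotted in —
and fiber-type estimation inverts that single line rather than refitting
area on carnosine, so one `CalibrationModel` object serves both the
estimate and the secondary-axis construction. Prediction intervals use the
classical Fieller inversion of the calibration line's prediction band,
which propagates both the new measurement's residual scatter and the
fitted-line uncertainty; simulation shows nominal 95 % intervals covering
the truth in 93–97 % of replicates at n = 12. When the slope is not
distinguishable from zero at the requested level the interval is reported
as unbounded (then clamped to the physical 0–100 % range with a flag)
rather than silently truncated.

**Summary t-tests.** Base R has no summary-statistic t-test, so
`summaryTTest()` implements the textbook pooled and Welch forms; the pooled
variant is the default because recomputing the published ex-athlete
contrast from its printed summaries (5.11 ± 1.07 vs 3.61 ± 0.81, n = 7/7)
under pooling reproduces the published p = 0.012 exactly after rounding.
All p-values are two-sided; the 0.05 threshold never gates computation,
only reporting.

**Pearson p-values: t transform vs permutation.** `pearsonCorrelation()`
reports the classical p from $t = r\sqrt{(n-2)/(1-r^2)}$. A permutation
test conditions on the observed sample and estimates a *different* (though
asymptotically equal) quantity; at n = 12 the two typically differ by a few
10⁻³ — larger than the Monte-Carlo error of a 100,000-draw oracle — and at
n = 5 the permutation distribution has atoms of size 1/120, so exact
agreement is impossible in principle. The property suite therefore asserts
agreement within max(3 Monte-Carlo SDs, 0.6/n), which is what the t
approximation actually guarantees at these sample sizes.

**Sigmoid fitting.** The four-parameter logistic is parameterized on
log₁₀(distance) with d50 in meters, so the curve's midpoint is a direct
parameter readout. Multi-start initialization covers d50 ∈ {300, 1000,
3000} m plus the data median and two hill starts; the fit is invariant to
point order and to km-vs-m unit changes (up to the d50 unit), and
degenerate inputs (fewer than five points, non-positive distances) error
early. A span of less than one decade of distance triggers a warning, as
d50 is then poorly constrained.

# Problem sizes

The test suite exercises the full chain at the sizes a desk check can
afford: 200-subject cells for the pipeline recovery study (two independent
acquisitions per subject, averaged, emulating the bilateral protocol), 200
seeded repeats for the test-retest CV, 500 twelve-subject calibration sets
for slope/intercept recovery, 1000 replicates for interval coverage, and
200 runner panels for d50 recovery. `scripts/acceptance.R` re-runs the two
200-subject cells and the water-linewidth check from a single seed.

# Limitations

* The calibration between carnosine and fiber type is anchored on a small
  (n = 12) biopsy sample in the emulated study; the package propagates that
  uncertainty through prediction intervals but cannot shrink it.
* Absolute quantification inherits any error in the configured relaxation
  times and temperatures; these are study-specific inputs, and the defaults
  are literature-guided placeholders, not measurements.
* Carnosine is an indirect fiber-type proxy: chronic vegetarianism or
  beta-alanine supplementation shifts muscle carnosine without changing
  fiber composition, and no spectral analysis can correct for that.
* The synthetic spectra omit scanner artifacts (see above), so real-data
  performance depends on acquisition quality — most critically shim (water
  linewidth) and water suppression.
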