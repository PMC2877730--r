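---
title: "Internal-standard quantification of AKH in direct MALDI-TOF profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-standard quantification of AKH in direct MALDI-TOF profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akhquant)
```

## The measurement model

Direct tissue profiling places a dissected corpora cardiaca (CC) on the
MALDI target, adds matrix, and acquires a spectrum of whatever diffuses
into the co-crystal. In the 990–1220 Da window of a single CC this is
essentially three species: mature AKH (pGlu-LTFSPDW-amide), its
carboxypeptidase intermediate AKHGK (free acid, Gly-Lys extension), and the
spiked heavy standard AKH* (AKH with leucine as ^13C~6~,^15N). Each species
appears as up to three singly charged cation adducts ([M+H]+, [M+Na]+,
[M+K]+), each with its isotopologue envelope.

Raw MALDI intensities are not quantitative: crystallization heterogeneity
and ion suppression rescale whole spectra unpredictably. The
isotope-dilution design removes exactly this nuisance: a chemically
identical standard is co-crystallized at a known amount
$n_\mathrm{std} = c_\mathrm{std} \times V_\mathrm{matrix}$ (400 nM × 200 nl
= 80 fmol), and the analyte amount is estimated with a unity-slope model

$$\hat n_\mathrm{analyte} \;=\; \frac{\sum_a I_{\mathrm{analyte},a}}
  {\sum_a I_{\mathrm{std},a}} \times n_\mathrm{std},$$

where the sums run over the assigned monoisotopic adduct peaks and $I$ are
relative intensities (peak over base peak of the processed spectrum). Any
spectrum-wide factor — suppression, laser power, the base-peak
normalization itself — cancels in the ratio. The unity slope assumes the
heavy and light peptides ionize identically, which holds to first order
because they are chemically identical; the small residual biases the
package does model are discussed below.

## The synthetic-data generator: what it emulates

`simulate_spectrum()` stands in for the instrument so every processing
stage can be tested against known ground truth. Its stated world:

* **Peaks.** Gaussian profiles with FWHM = m/z ÷ resolving power
  (default 8000, a typical reflectron TOF; the source acquisition does not
  state one), rendered per isotopologue from the exact envelope of the
  species' elemental composition. Peak area is proportional to effective
  concentration × adduct fraction × the per-spectrum suppression factor.
* **Amount → concentration.** A CC's `a` fmol dissolved in `V` nl of
  matrix is `1000·a/V` nM (174 fmol in 200 nl ≈ 870 nM); the standard
  enters directly in nM.
* **Adduct partition.** Defaults (generator conventions, not measured
  claims): AKH and AKH* 0.05/0.55/0.40 over H/Na/K — protonated AKH is
  nearly absent from CC profiles — and AKHGK 0.35/0.40/0.25, since the
  free acid also protonates.
* **Ion suppression.** One shared log-normal factor per spectrum
  (σ = 0.5, mean 1). The internal-standard design corrects exactly this
  shared factor; species-specific suppression is out of scope.
* **Saturation.** Effective concentration is `c/(1 + c/c_sat)` per
  species, `c_sat = 20 µM`. This default is a deliberate choice: it keeps
  the proportional response at physiological loads (≤ 1 µM, bias ≤ 2.5%)
  while making a 5 µM standard overload depart from the 1/c calibration
  law by ~25%, so a finite linear range (50–500 nM observed) is
  reproducible. A much smaller `c_sat` (e.g. 1 µM) would contradict the
  observed unity-slope behaviour at ~870 nM tissue loads — the ratio would
  be biased by 25% — so it cannot describe the same instrument.
* **Baseline, noise, acquisition.** Exponential chemical baseline
  (amplitude 20, decay 100 Da, strongest near the matrix region);
  Gaussian detector noise (sd 2 per subspectrum) averaged over five
  subspectra, emulating the five-subspectra × 50-shot acquisition at the
  realization level (shot-level physics is not attempted); intensities
  below the 850 Da low-mass gate are zeroed.

**What it does not emulate:** matrix cluster chemistry, mass-calibration
drift, species-specific suppression, detector clipping, and shot noise.
A green test therefore establishes that the *processing and statistics*
recover the stated world; it cannot certify instrument-specific effects
outside that world.

Cohorts draw per-fly amounts log-normally, moment-matched to a requested
mean/sd — biological amounts are positive and right-skewed, and the
published day-5 dispersion (sd ≈ 0.3 × mean) makes the log-normal a
natural choice. `fix_mean = TRUE` rescales a drawn cohort so its
ground-truth sample mean is exact, for recovery experiments where the
cohort mean is the controlled quantity rather than a random variable.

## Processing: choices and numerical details

* **Baseline.** Morphological top-hat (rolling minimum then rolling
  maximum, window 5 Da — several times the ~0.13 Da peak FWHM but narrower
  than baseline curvature). The opening runs *under* the noise band,
  leaving a positive pedestal after subtraction; the S/N estimator accounts
  for this by measuring apexes from the local median level.
* **Peak detection.** Local maxima with S/N ≥ 3 (the detection threshold
  that defines a "detected" species; the source protocol states none).
  Noise is the scaled MAD of signal-free intensities in 15 Da tiles;
  only unambiguous peaks (≥ 10 σ) are excluded from the noise set, because
  excluding every 3 σ excursion would bias the MAD low and inflate S/N.
  Apexes are refined by a three-point parabola on log intensities, which
  is exact for a Gaussian and yields position, width and height.
* **Intensity = area.** Reported peak intensity is the area-equivalent
  height × width × √(2π). On a TOF, width grows ∝ m/z at constant
  resolving power, so raw apex heights would under-weight heavier species
  by up to ~18% across the processed window and bias AKHGK/AKH* ratios;
  integrated intensities remove this. S/N still uses the apex height.
* **De-isotoping.** Greedy left-to-right chaining at spacing
  1.00335 ± 0.05 Da, ties broken by smaller spacing error, intensities
  non-increasing after the envelope maximum, and a ≤ 3× rise per step
  before it. The cap rejects chains in which a noise bump one unit below
  a real monoisotopic peak would swallow it; real CHNOS envelopes below
  1.5 kDa never step up more than ~0.9×. This is a documented
  simplification of full envelope fitting.
* **Adduct assignment.** Each species' three candidate m/z values match
  the nearest unassigned monoisotopic peak within 0.2 Da (externally
  calibrated MALDI-TOF); conflicts resolve by smallest mass error, and
  cross-species coincidences are recorded as ambiguity notes on the group.
* **Window.** Only 850–1500 Da is processed, honouring the low-mass gate.

Degenerate inputs: all-zero spectra yield empty peak lists; noise-free
spectra yield infinite S/N (everything real is detected); a sample whose
standard is undetected gets `NA` ratios and is excluded from summaries but
counted in the QC tally, never silently dropped.

## Quantification and calibration

Amounts are `ratio × 80 fmol` exactly (unity slope); the fitted calibration
constant is a *diagnostic*, not a correction. With the analyte held fixed
and the standard diluted, the ratio follows `k/c`; `fit_calibration()`
estimates `k` by least squares of ratio on `1/c` through the origin and
reports the maximal contiguous run of concentrations within 15% relative
deviation of `k/c` as the linear range. "Linear" is thus read as constancy
of ratio × concentration — the natural form for an internal-standard
dilution — and `k` should recover the analyte's equivalent concentration
(it does, to < 1%, when the analyte sits well below saturation; the
calibration experiments here use a day-1-level analyte of 38 fmol ≈
190 nM, matching the young flies used for standard curves).

Known, documented biases of the full chain: the standard's own 2%
saturation at 400 nM and the analyte's load-dependent saturation put a
−2 to −3% systematic error on day-5-level amounts (870 nM); faint
high-order isotopologues fall below the noise floor for analytes under
~25 fmol, costing up to another ~2%. Both are small against the ±10–15%
acceptance envelopes and are asserted quantitatively in the test suite.

## Statistics

Cohorts are summarized the way the field reports them: detection rates
over all samples; *median* ratios (robust to the skewed per-fly
distribution); *mean ± s.e.m.* amounts. Group comparisons use the
Mann-Whitney U with midranks; the two-sided p is exact — full null
distribution by the subset rank-sum counting recursion — whenever
`nA·nB ≤ 400` with no ties (covering every cohort size used here), and a
normal approximation with tie and continuity corrections otherwise.
Sidedness is not stated in the source analyses; two-sided is the
conservative default. Stars at 0.05/0.01, no multiple-testing correction
(none is applied in the source workflow).

## Design decisions that were genuinely open

* **"Mw = 982.5 Da" for the standard.** The package computes neutral
  monoisotopic 981.467, [M+H]+ 982.474, and average 982.00. Only the
  singly protonated monoisotopic mass rounds to the printed 982.5, so that
  reading is adopted.
* **Pyroglutamate timing.** The intermediate AKHGK is observed at
  1160.550, i.e. *with* pyroglutamate; the model therefore cyclizes an
  exposed N-terminal Gln on every post-convertase intermediate rather than
  only at amidation.
* **Heavy labels as atom substitutions.** AKH* carries six ^13C and one
  ^15N as distinct atoms, so its envelope is computed from the remaining
  *light* atoms — narrower than AKH's envelope (second/mono 0.49 vs 0.56),
  not merely shifted.
* **Which group is n = 15.** The day-5 comparison reports n = 15/16
  without assigning them; the generator takes control = 15, mutant = 16.
* **Cohort parameters for the day-5 control.** The published day-5 table
  splits by sex (174 ± 49 fmol, n = 3 males; 178 ± 54, n = 13 females);
  the mixed-sex simulated cohort pools them by sample size
  (mean 177.25, sd 53.3). The printed dispersions are used directly as
  per-fly sds of the generator.
* **Electron mass** is included in adduct shifts (< 0.001 Da, below every
  tolerance, but free to get right).

## Limitations

Charge states above +1, overlapping-envelope deconvolution,
recalibration, species-specific suppression, shot-level acquisition
physics, matrix-matched absolute calibration, and IUPAC limits of
quantification are out of scope. Detection rates near the limit of
detection depend on the stated noise model and should not be read as
instrument predictions.
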