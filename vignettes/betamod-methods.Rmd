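---
title: "Beta ERD/ERS quantification and fatigue modelling with betamod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta ERD/ERS quantification and fatigue modelling with betamod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific background

During a cued voluntary movement, power in the beta band (here 13.5–25 Hz)
over sensorimotor and frontal scalp first drops below its pre-movement level
(event-related desynchronization, ERD) and then, after movement offset,
overshoots it (event-related synchronization, ERS, the "beta rebound").
The peak-to-peak span of this modulation — **modulation depth = peak ERS −
peak ERD**, in baseline-relative units — indexes how strongly the
sensorimotor system engages and disengages.

In people with multiple sclerosis (MS), reduced beta modulation depth,
especially over frontal scalp, has been associated with subjective fatigue:
fatigued patients (MS-F) show shallower modulation than non-fatigued
patients (MS-NF) and healthy controls (HC), and depth correlates negatively
with fatigue severity (FSS), and with intracortical facilitation and deep
grey-matter volumes. `betamod` implements the full quantification pipeline
for this biomarker, the group-level statistics used to test it, and a
cross-validated classifier that asks whether multimodal features (including
depth) separate fatigued from non-fatigued patients.

Because real patient EEG cannot ship with a package, `betamod` includes a
seeded synthetic generator that emulates the study design closely enough to
exercise — and validate against known ground truth — every stage of the
pipeline.

## Pipeline overview

For one recording session (one subject):

1. **Band-pass and epoching** (`eeg_bandpass_notch()`, `eeg_epoch()`):
   zero-phase Butterworth band-pass (plus mains notch) of the continuous
   EEG, then epochs of −0.5 to +1.5 s around each cue at 256 Hz.
2. **EMG trial validation** (`emg_session_metrics()`,
   `apply_joint_exclusion()`): rectification about the channel mean, a
   low-pass envelope whose cutoff is widened by 25% to compensate for the
   bandwidth narrowing of forward–backward filtering, and a
   threshold-and-minimum-run onset detector. Trials without a credible
   contraction are dropped from both EMG and EEG.
3. **Current source density** (`csd_transform()`): spherical-spline surface
   Laplacian (spline order m = 4, regularization 1e-5, 50-term Legendre
   series) applied as a precomputed channels × channels matrix. CSD is
   reference-free: it maps any constant topography to zero, so a change of
   recording reference does not change the output.
4. **Time–frequency decomposition** (`morlet_tfr()`): complex Morlet
   wavelets at 1–90 Hz in 0.5 Hz steps (179 bins), with cycles increasing
   linearly from 3 at 1 Hz to 10 at 90 Hz, evaluated on a 10-ms output
   grid. Kernels are L1-envelope-normalized so a unit-amplitude real
   sinusoid yields peak power ≈ 0.25 at its own frequency. Edge-contaminated
   time–frequency points (within one kernel half-length of the epoch
   border) are flagged.
5. **Baseline normalization** (`baseline_normalize()`,
   `beta_timecourse()`): beta-band power is normalized per trial and
   channel as (P − μ)/μ with μ the mean over the *whole* epoch. This
   "subtract and divide by the same mean" choice makes the time-mean of
   every normalized trace exactly zero — a machine-precision invariant the
   test suite checks at 1e-10.
6. **Personalized ROI and metrics** (`session_beta_metrics()`): within each
   candidate region (frontal, left and right sensorimotor electrode lists
   that share the midline), the electrode with the largest trial-averaged
   modulation depth is selected as the peak; the ROI is that electrode plus
   its six nearest neighbours on the full montage (ties broken by distance
   then label). Per-trial peak ERD (minimum over [0, 0.7) s), peak ERS
   (maximum over [0.7, 1.0] s), their latencies and the depth are then
   re-extracted from the ROI average.

At the cohort level, `kw_test()` / `dunn_posthoc()` compare groups,
`spearman_boot()` gives bootstrap confidence intervals for rank
correlations, `std_regression()` reports standardized betas,
`mediate_boot()` runs bias-corrected bootstrap mediation, and
`fatigue_nested_cv()` + `stability_refit()` fit the elastic-net fatigue
classifier under repeated stratified nested cross-validation.

## The synthetic generator

`sim_scenario()` freezes the study conditions; `generate_session()` draws
one subject's EEG + EMG session and `generate_cohort()` draws the
three-group feature table.

### Session EEG

Each trial is 1/f background noise (power-law spectrum, slope ≈ 1) on all
61 electrodes plus, for each region, a beta-band carrier whose envelope
follows the planted ERD/ERS time course (smooth dips to the ERD target
around 0.3 s and rebound peaks around 0.85 s), spatially weighted by a
Gaussian topography (`topo_sigma = 0.22` on the unit sphere) centred on the
region's nominal peak electrode.

The measured depth after the full pipeline is not the planted envelope
depth: the band-pass, CSD and wavelet stages attenuate the carrier, and the
1/f background dilutes the baseline-relative units. The generator
compensates in three stages, all decided at design time and frozen:

1. an **envelope fixed point** against the pipeline's forward response, so
   the normalized single-channel time course hits the requested ERD/ERS
   values;
2. a **background dilution** correction estimated from a handful of
   carrier-free trials passed through the same session pipeline; and
3. a frozen per-region **`recovery_gamma`** gain (e.g. frontal ≈ 1.17,
   sensorimotor ≈ 1.25–1.30) absorbing the residual interaction between
   topography, CSD and ROI averaging.

With these in place, 300-trial sessions recover the planted per-region
depths to within a few hundredths of a baseline-relative unit, and the
package asserts ±0.15 in its acceptance tests. The per-session `truth`
tibble records the planted values so recovery can always be checked.

### Session EMG

EMG trials carry a noisy tonic baseline plus, on non-"noise" trials, a
contraction burst with known onset; a configurable fraction of trials is
burst-free and should be caught by the exclusion rule. Ground-truth onsets
(`onset_true`) and the noise-trial flag ship with the object.

### Cohort features

`generate_cohort()` draws group sizes 19/22/18 (MS-F / MS-NF / HC) by
default. Per-group depth means follow the scenario's `group_params`
(frontal 3.53 / 4.20 / 4.07). Clinical, neurophysiological and volumetric
covariates are drawn through a Gaussian copula so that planted Spearman
correlations (e.g. FSS vs frontal depth ρ = −0.54) hold exactly in the
latent model; rank targets are converted to latent Pearson correlations via
2·sin(πρ/6) and the joint matrix is checked for positive definiteness at
validation time. FSS defines the fatigue label by the usual cutoff, and HC
subjects have missing patient-only scores.

## What the generator does and does not emulate

Emulated: cue-locked beta ERD/ERS dynamics with group differences, 1/f
background EEG on a realistic 61-electrode montage, EMG bursts with
catchable bad trials, and a correlated multimodal feature table with a
separable (but not trivially separable) fatigue label.

Not emulated: eye/muscle artifacts, electrode bridging or drift, volume
conduction from realistic cortical sources, non-stationary alpha/mu
rhythms, trial-to-trial latency jitter in the hemodynamic sense, or any
within-subject session-to-session variability. Correlations among features
are planted at the latent Gaussian level, so observed finite-sample rank
correlations scatter around the targets. The generator is a validation
harness, not a forward head model.

## Numerical choices

* **Whole-trial normalization** makes the epoch-mean identity exact and
  sidesteps the choice of a pre-cue baseline window; the cost is that ERD
  and ERS magnitudes are relative to the whole-epoch mean, not to rest.
* **Half-open windows**: the ERD window is [0, 0.7) s and ERS [0.7, 1.0] s,
  so the 0.7 s sample belongs to ERS only — no sample is scored twice.
* **The 10-ms TFR grid is snapped to sample times** (maximum deviation half
  a sample), giving 200 points on the [−0.5, 1.5) epoch at 256 Hz.
* **CSD regularization** λ = 1e-5 with m = 4 follows common practice; the
  transform is validated against a dense brute-force spherical-spline
  solver (bordered system with a constant term) to 1e-6, and its
  reference-invariance and zero-on-constants contracts to 1e-8.
* **Elastic net**: α over 0.1–1.0, ~100 log-spaced λ values spanning four
  decades below the data-driven λ_max, inner selection by cross-validated
  binomial deviance, predictors z-scored on each outer training set only.
  The descriptive refit uses a small ridge penalty for stability at n ≪ p
  resolutions and reports bootstrap odds-ratio intervals and pseudo-R².
* **Mediation** uses bias-corrected (BC, not BCa) percentile bootstrap
  intervals. BC intervals are known to be slightly liberal for the indirect
  effect when the a-path is strong and the b-path is null; measured null
  coverage in this implementation is ≈ 93–94% rather than 95%, which is
  documented rather than corrected, and the acceptance check bands coverage
  accordingly.

## Limitations

* The generator's compensation constants (`recovery_gamma`) are calibrated
  for the default pipeline settings; changing wavelet cycles, the CSD
  regularization or the beta band will bias depth recovery until they are
  recalibrated.
* Kruskal–Wallis p-values use the chi-square approximation; at very small
  groups (n = 4) it deviates from the exact permutation null by up to a few
  hundredths, as the tests document.
* The fatigue classifier's stability selection is honest about noise: pure
  noise predictors can still reach moderate selection frequencies at small
  n, so selection frequency should be read comparatively, not as a
  significance test.
* Region names follow the package convention `frontal`,
  `left_sensorimotor`, `right_sensorimotor` throughout; mapping to other
  atlas or montage nomenclatures is the user's responsibility.

## Reproducing the headline numbers

The repository ships `scripts/acceptance.R`, which regenerates every
headline quantity (depth recovery per group and region, EMG exclusion
rates, bootstrap correlations, group tests, mediation, detection power and
the cross-validated classifier metrics) from a single seed:

```sh
Rscript scripts/acceptance.R --seed 7 --out acceptance.json
```

The test suite (`testthat::test_dir("tests/testthat",
load_package = "installed")`) checks the same contracts at fixed seeds and
tolerances.
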