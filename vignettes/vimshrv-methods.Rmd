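---
title: "Methods: cardiac assessment of visually induced motion sickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiac assessment of visually induced motion sickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vimshrv)
```

## The problem and the model

Visually induced motion sickness (VIMS) arises from visual–vestibular
conflict while viewing immersive VR content on a head-mounted display.
Its autonomic signature is measurable in heart rate variability: the
sympathetic-linked very-low-frequency band (VLF, 0.0033–0.04 Hz) of the
RR-interval spectrum rises, the parasympathetic-linked high-frequency
band (HF, 0.15–0.4 Hz) falls, and the time-domain indices SDNN and
pNN50 fall. `vimshrv` implements the full chain from raw single-lead
ECG to (a) per-recording feature vectors, (b) a nine-zone
autonomic-balance classification of the normalised (ln VLF, ln HF)
plane, (c) covariate-adjusted cohort statistics against Simulator
Sickness Questionnaire (SSQ) scores, and (d) a permutation-validated
binary MS classifier, together with a synthetic-data module that
emulates the underlying within-subject 2D-vs-VR experiment.

The intended design is: each subject views the same content in a 2D
(control) and a VR (MS-inducing) condition, with ECG and SSQ collected
before and after each viewing. Post-viewing outcomes are compared
between conditions with the pre-viewing state as covariate.

## Signal path and its assumptions

**Band-pass filter.** A 3rd-order Butterworth band-pass (5–15 Hz)
applied forward–backward. Only the passband is fixed by the reference
procedure; we chose the Butterworth/zero-phase realization because any
phase distortion would bias R-peak times. The design (analog prototype,
low-pass-to-band-pass transform, bilinear transform) was verified
against an independent DSP reference to machine precision; the
coefficients are frozen in the test suite. Zero-phase filtering uses
odd-reflection padding of three filter lengths, so records must exceed
18 samples.

**R-peak detection.** The classic derivative–squaring–integration
detector with adaptive dual thresholds: 150-ms integration window,
200-ms refractory period, search-back at 1.66 × the running RR mean.
Two implementation details matter. First, ripple maxima on the
integrated QRS mound are collapsed to the single largest candidate per
refractory neighbourhood before thresholding; without this, a leading
ripple can be accepted and the true peak rejected as refractory.
Second, detections are refined to the local maximum of the *unfiltered*
record within ±50 ms, so reported R times are morphology-true. All
constants are exposed in `qrs_config()`.

**NN filtering.** RR intervals outside 600–1200 ms are excluded, not
interpolated. The bounds are treated as *inclusive*; the source
procedure writes the range without open/closed qualification. Survivors
keep their original onset times, and the later spline resampling simply
bridges the gaps — the reference procedure excludes artifacts without
describing gap handling, and bridging avoids inventing beats.

**Tachogram and spectrum.** The NN series is cubic-spline interpolated
(`splinefun`, "fmm") onto a uniform 4-Hz grid and analysed with a
single full-segment Hann-windowed FFT. We deliberately do not use Welch
segmentation: the procedure names a plain "FFT, Hanning window", and on
5–12-minute records the full segment maximises VLF resolution, which is
the scarce resource (one cycle of the 0.0033-Hz edge takes ~300 s;
`band_powers()` warns on shorter records).

**Parseval normalisation (a deliberate choice).** A Hann periodogram
with textbook window-power compensation only matches the series
variance in expectation; on finite random input the mismatch is
O(1/sqrt(N)), several percent at N ≈ 1200. Because the package contract
requires the PSD integral to equal the variance of the de-meaned series
to 1%, the PSD is rescaled so the identity holds *exactly*. This leaves
band-power ratios untouched and makes total power interpretable as
variance.

**Log features.** ln VLF and ln HF with a floor of 1e-12 ms² inside the
log so degenerate inputs stay finite (with a warning). The ratio
feature is read literally as the quotient of logs, ln(VLF)/ln(HF) — not
ln(VLF/HF) — because that is what the feature's name says; the
alternative is available via `ratio_mode = "log_of_ratio"`. The
quotient convention makes the ratio sensitive to the sign of ln HF;
with band powers well above 1 ms² (the realistic regime) it is
well-behaved.

**SDNN** uses the sample (n−1) standard deviation; the source does not
specify the denominator. **pNN50** counts strictly greater than 50 ms.

## Autonomic zones

The (ln VLF, ln HF) plane is trisected per axis into low/normal/high
and mapped to eight labelled zones around a central reference zone
(e.g. Zone 5 = high sympathetic / low parasympathetic, the expected
post-VR destination; Zone 1 = the parasympathetic-dominant opposite
corner). Numeric boundaries are *not published*, so `zone_config()` is
mandatory-configurable and `zone_config_from_reference()` derives
stand-in thresholds from a reference cohort's 25th/75th percentiles —
documented as a stand-in, not a literature value. Boundary points
resolve by a closed-interval convention: values equal to a threshold
are "normal", making the map a true partition.

## SSQ scoring

Sixteen items rated 0–3 feed three overlapping factors (7 items each;
e.g. general discomfort is in N and O, difficulty focusing in O and D).
Weighted scores are N × 9.54, O × 7.58, D × 13.92 and total
(N + O + D) × 3.74. The total-score formula is typeset ambiguously in
the source ("N+O+D×3.74"); we follow the canonical Kennedy convention
(N + O + D) × 3.74, under which the published subscale/total weights
are mutually consistent. The membership matrix is exposed read-only via
`ssq_items()`. The source lists 7 symptoms per factor against 16 items
total; the canonical 16-item list with overlapping memberships is the
only layout consistent with both statements and is the one hard-coded.

## Cohort statistics

`ancova()` fits `post ~ baseline + group` with homogeneous slopes (no
interaction term — slope homogeneity is assumed, not tested, matching
the reference analysis) and F-tests the group term with df = (1, n−3);
ηp² comes from the sums of squares and equals F·df1/(F·df1+df2).
Within-subject dependence between a subject's 2D and VR rows is
*ignored* in the F test. That is statistically unorthodox, but it
reproduces the reference degrees of freedom (F(1, 53) from 28 subjects
× 2 conditions) and is kept as fidelity-over-orthodoxy; the
type-I-error calibration test shows the test holds its nominal level
under the generator's null, where rows are exchangeable.

Bonferroni families: α = 0.05/4 = 0.0125 for the four SSQ scores,
α = 0.05/6 ≈ 0.0083 for the six cardiac features (computed exactly,
printed rounded). Effect sizes bin at 0.01/0.06/0.14; correlations at
0.10/0.40/0.70/0.90.

`partial_correlation()` correlates least-squares residuals with
df = n−3. For the SSQ-vs-feature analysis each variable is residualized
on its *own* pre-viewing baseline (the reference plots "residuals" of
both variables); the classic single-covariate form — which equals the
textbook closed form — is the default signature.

## Classification

Features are exactly the five significant indicators (SDNN, pNN50,
ln VLF, ln HF, ln VLF/ln HF); heart rate is excluded. The four
classifiers run at fixed, published hyperparameters (KNN k = 28
Euclidean; tree with ≤ 2 deviance-reduction splits; linear SVM with
box constraint C = 0.0706; hyperparameter search is out of scope).
Because the environment provides no ML library for these, all four are
implemented in-package: pooled-covariance LDA, vectorised KNN, an
exhaustive-search tree, and a dual-coordinate-descent linear SVM
(deterministic sweep order, bias via feature augmentation). The test
suite checks LDA against an independent reference implementation and
AUC against the Mann–Whitney identity.

Decisions the source leaves open, fixed here and configurable:

* **Positive class = VR** (the MS state), so recall is the fraction of
  VR recordings recognised.
* **Stratified folds** drawn from a caller-supplied seed.
* **Standardization inside each training fold** (leakage-safe), using
  training parameters on the test fold. The source's phrasing may
  describe global scaling; per-fold is the defensible default, and
  `standardize = FALSE` plus external scaling reproduces the global
  variant.
* **KNN ties** (14 vs 14 with k = 28 on 56 observations) resolve by the
  single nearest neighbour's label.
* **Permutation statistic** is the CV accuracy with the add-one
  p-value (1 + #{null ≥ observed})/(1 + B); the source names neither
  the statistic nor the formula. p can never drop below 1/(B+1).

## The synthetic world

The generators define the "stated world" in which everything is tested;
the study's raw recordings are not publicly available, so nothing here
is calibrated to them.

* **RR series**: additive sinusoidal modulation,
  RR(k) = mean ± VLF and HF sinusoids + white jitter, evaluated at
  cumulative beat times. Chosen over integral-pulse-frequency
  modulation because each sinusoid contributes an *exactly known* band
  power a²/2 — the lever for spectral-recovery testing. IPFM would be
  the natural extension for physiological realism.
* **ECG**: a sum-of-5-Gaussians P-QRS-T template per beat plus baseline
  wander (~0.3 Hz), 60-Hz line interference and white noise, with
  ground-truth R times (a 0.5-s lead-in keeps the first complex whole).
  Morphology realism is explicitly *not* a goal — exercising the
  detector is; there are no ectopics, no template variability, no
  electrode artifacts.
* **SSQ**: a cumulative-threshold ordinal model (thresholds 0.5/1.5/2.5,
  latent noise SD 0.6) monotone in a latent severity; the source gives
  no item-level response model.
* **Cohort**: 28 subjects by default (the study's n); four cells per
  subject; a shared subject-level component gives pre/post correlation
  0.7; programmed shifts (defaults −2, −2, +2, −2 between-subject SDs
  on SDNN, pNN50, ln VLF, ln HF) applied to VR-post only; heart rate
  carries no effect; ln ratio is always computed, never drawn; SSQ
  severity is coupled to the mean programmed effect under VR-post. The
  ±2 SD defaults are *testability stand-ins*: the reference publication
  plots per-condition means but prints no effect sizes, so no value can
  be study-calibrated. In `mode = "rr"` each cell also carries a
  generated RR series whose sinusoid amplitudes reproduce the cell's
  band powers, for end-to-end runs.

A green test against this world establishes that the pipeline recovers
known spectral/statistical structure and that the statistics are
calibrated under the generator's null. It does **not** establish
performance on real ECG (artifacts, ectopy, non-stationarity) nor the
study's human-subject effect sizes.

## Real-time monitor

The monitor slides a 300-s window (the shortest resolving the VLF edge)
at a 10-s stride, extracts features per window, optionally assigns the
autonomic zone, and applies a trained classifier for a binary
MS/normal decision. Failed windows (e.g. flat signal) are logged as
`invalid` with the reason, never dropped. The GUI and hardware
synchronization of the original system are out of scope; a start-time
offset and file input replace them. Decisions after a regime switch
stabilise within one window length — the inherent latency of windowed
features.

## Numerical choices and degenerate inputs

* Permutation seeds, fold seeds and generator seeds all flow from
  caller-supplied integers; every generator restores the caller's RNG
  state.
* `ln` floor 1e-12 ms²; ln ratio undefined (explicit error) only when
  ln HF is exactly 0 in quotient mode.
* Empty NN series: warning at the filter, explicit error at every
  consumer.
* The SVM solver stops at max |Δα| < 1e-10 or 1000 epochs; with ~50
  standardized training rows it converges far earlier.
* Tree splits need a deviance reduction > 1e-12; ties in split search
  resolve to the first (lowest feature index, lowest threshold).

## Known limitations

* Additive-sinusoid RR generation has no respiratory–cardiac coupling
  or 1/f background; pNN50 under the generator is driven mostly by the
  jitter term.
* The ANCOVA intentionally ignores the within-subject pairing (see
  above); a mixed model would be the orthodox alternative.
* Zone thresholds must be supplied or derived from a reference sample;
  none ship as constants.
* The LF band (0.04–0.15 Hz) and nonlinear HRV indices are out of
  scope, as is Bayesian hyperparameter optimization.
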