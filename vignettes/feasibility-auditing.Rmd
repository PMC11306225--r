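---
title: "Auditing the feasibility of waveform-to-vital prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the feasibility of waveform-to-vital prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecheck)
```

## The question this package asks

A recurring pattern in wearable-health research is to record a sensor
waveform (here the photoplethysmogram, PPG), record a gold-standard label
(systolic blood pressure, SBP, from an arterial line or cuff), and train a
regression model from one to the other. Before investing in models, two
questions deserve an answer:

1. **Is the map single-valued?** If two windows of signal are essentially
   identical but carry labels far apart, *no* function of the input can
   predict both correctly. The fraction of windows with such a
   "multi-valued" partner bounds the achievable accuracy from below.
2. **How much label information does the input carry?** The mutual
   information (MI) between input features and the label, divided by the
   label's entropy — the *Info-Fraction* — measures the share of label
   uncertainty the input can ever resolve, independent of any model class.

`pulsecheck` implements both measures together with the audit procedures
that commonly inflate reported accuracy when ignored: train/test leakage
across patients, records or raw samples; over-constrained label ranges;
per-record calibration evaluated only at short time scales; and aggressive
signal-quality filtering.

## The multi-valued-mapping checker

Records are cut into non-overlapping 2-s windows (250 samples at the
canonical 125 Hz). For a window pair, the second window is circularly
shifted by the lag (within ±0.5 s) maximizing the normalized
cross-correlation of the mean-removed windows — for circular shifts this
lag also minimizes the Euclidean distance — and the distance is the L2 norm
of the aligned difference. A window is *matched* if some window in scope
(same patient, or different patient) is within an input distance of 1.0
while its label differs by at least the output threshold (8 mmHg for SBP,
8 bpm for HR, 0.02 s for RWAT). The report counts matched windows, not
pairs; both scopes use all labeled windows as denominator.

Numerical choices:

* Windows are min-max normalized **per record** (not per window) before
  distances: PPG units are arbitrary, and the 1.0 threshold (4e-3 mean
  square per sample) is only meaningful on a bounded scale, while relative
  amplitude *within* a record is informative and preserved.
* The distance 1.0 is interpreted as an L2 norm over all 250 samples;
  1.0² / 250 = 4e-3 recovers the per-sample mean-square reading.
* Thresholds are inclusive; the alignment tie-break prefers the smallest
  |lag| (search order 0, +1, −1, ...). Circular shifting keeps the vector
  length fixed; wrap-around edge effects are accepted and affect at most
  ±0.5 s of content.
* The O(n²) scan can pre-screen pairs with two lower bounds that hold
  under any circular shift — the L2 distance of the magnitude spectra
  (Parseval and the per-frequency triangle inequality) and of the sorted
  sample vectors (rearrangement inequality) — with a relative margin of
  1e-9 so floating-point accumulation can never drop an exact-boundary
  pair. The pre-screen is exactness-preserving and is tested against an
  exhaustive R-level double loop.

## Mutual information and the Info-Fraction

Continuous MI is estimated with the classic k-nearest-neighbour estimator
(first variant) on standardized columns, k = 3 by default (the estimator's
common practice; the choice matters little between 3 and 10), with seeded
jitter of 1e-10 column SDs to break ties. The estimate is clamped at 0.

Making MI comparable with a *target entropy* requires care: differential
entropy is scale-dependent and can be negative, so a ratio against it is
not meaningful. The package therefore quantizes the target at sensor
resolution (1 mmHg, 1 bpm, or 0.01 s) and uses a mixed
continuous–discrete neighbour estimator for the numerator: for each point,
the distance to its k-th neighbour *within its own label class* defines a
radius whose occupancy in the full sample is compared against the class
size. Numerator and denominator then refer to the same discretized
variable, the ratio is clamped to [0, 1], and a deterministic
feature-to-label map yields an Info-Fraction near 1. The fully continuous
estimator remains available via `mi_config(estimator = "ksg_continuous")`
for sensitivity analysis; this entropy convention is the main
reconstruction choice in the package and the first knob to vary when
comparing against other implementations.

## What the synthetic generator emulates — and what it does not

Every analysis is testable offline through `generate_cohort()`, which
renders multi-patient PPG/ABP/ECG records at 125 Hz with per-window ground
truth. The statistical structure is chosen to mirror what the audits
probe:

* **Per-patient traits.** SBP baseline uniform in 100–145 mmHg; resting
  heart rate uniform in 60–100 bpm (a patient trait, with ±2 bpm
  per-record jitter and slow within-record wander); pulse amplitude
  uniform in 0.8–1.2 a.u.
* **Within-record SBP.** An AR(1) process per 2-s window step with
  coefficient 0.99 and stationary SD 2 mmHg — resting SBP varies slowly
  and by only a few mmHg over minutes. This scale also defines the
  well-conditioned contract: at matched morphology, within-record label
  differences rarely reach the 8 mmHg output threshold.
* **Morphology coupling.** Each beat is a systolic Gaussian bump plus a
  smaller reflected bump delayed by the reflected-wave arrival time
  (RWAT). The PPG-visible SBP component moves RWAT (higher pressure →
  stiffer vessels → earlier reflection) and the systolic rise width
  (higher pressure → steeper upstroke), so handcrafted features genuinely
  carry SBP information in well-conditioned mode.
* **Planted ill-conditioning.** In `conditioning = "ill"` mode a latent
  component drawn i.i.d. per window from N(0, latent_sd²) moves SBP
  without touching the waveform. `latent_sd` is a direct, monotone dial on
  the multi-valued match fraction; i.i.d.-per-window sampling keeps the
  planted fraction analytically controllable.
* **Calibration drift.** Each patient receives a drift rate drawn from
  N(0, drift_per_day²) mmHg/day, *invisible* to the waveform. Two
  modelling decisions are deliberate here. First, drift is PPG-invisible
  (unlike the AR component): it stands for blood-pressure change from
  medication, lifestyle or vascular factors that a pulse shape cannot
  reveal — precisely the change that makes one-off offset calibration
  decay. If morphology tracked the drift, a feature-based predictor would
  follow it and no decay could be measured. Second, the drift *rate* is
  random per patient rather than one shared constant: a common rate shifts
  the error mean but leaves the error SD flat across day bins, whereas
  heterogeneous rates make the day-binned error SD grow — the quantity the
  decay audit reports.
* **Artifacts.** Baseline wander below 0.5 Hz, white noise, zeroed
  dropout gaps and stepwise amplitude jumps at Poisson times, mirroring
  the classic ICU-waveform failure modes.

The ABP channel is rendered so each systolic peak equals the true SBP of
the window the peak falls in, which makes `derive_labels()` exact up to
beat detection; ECG R-waves precede each systolic peak by the configured
pulse-arrival delay (0.20 s).

What the generator does **not** emulate: pathology-specific waveforms,
respiratory modulation, sensor-site differences, motion artifacts with
structure, or any validated hemodynamics. Passing tests on this generator
demonstrates that the *audit machinery* measures what it claims on data
with known ground truth — not that real PPG supports or fails any
particular prediction task.

## Preprocessing choices

The band-pass is a cascade of 4th-order Butterworth high-pass (0.5 Hz) and
low-pass (16 Hz) sections, each applied forward–backward for zero phase —
beat-relative timing features must not be skewed by filter delay. The
cascade is used instead of a single band-pass design because the very low
normalized high-pass edge (0.004 of Nyquist) makes a joint 8th-order
band-pass numerically fragile in transfer-function form.

The signal-quality score is the maximum, over physiologic lags 0.33–2 s
(30–180 bpm), of the Pearson correlation between the window and its
lag-shifted copy. Lags leaving less than half the window of overlap are
skipped: short overlaps produce meaningless correlations. A perfectly
periodic window scores ~1 regardless of window length; the "biased"
autocorrelation normalization (dividing by the full window length) was
rejected because it caps the score of a genuinely periodic 2-s window well
below 1. Zero-variance windows score 0 by definition.

The composite `Quality` feature averages three clamped components:
autocorrelation quality, the fraction of samples outside constant-value
runs of ≥ 80 ms (dropouts/clipping), and the mean pairwise correlation of
per-beat templates resampled to a common length. The exact composition of
such scores in commercial datasets is proprietary; this reconstruction has
documented, equal weights.

## Feature conventions

* Beat detection: local maxima above an interpolated rolling 75th
  percentile with a 0.33 s refractory interval, greedy by amplitude; peak
  positions are refined to sub-sample accuracy by parabolic
  interpolation — at 125 Hz one sample is 8 ms, and pulse-arrival times
  are reported to 10 ms. ECG R-peaks use a squared-derivative energy
  detector with the same refractory rule.
* HR is 60 over the *median* inter-beat interval; SDNN is the population
  SD of the intervals, and windows of a minute or longer are subdivided
  into 60-s sections whose SDs are averaged (the subdivision length is a
  documented choice; the convention's source leaves it open).
* The systolic ramp (dp/dt) takes, per beat, the slope from the upstroke
  onset (last sample within 10% of the valley-to-peak range before the
  peak) to the peak, multiplied by the beat duration (per-beat-fraction
  normalization). For a linear upstroke the measured slope equals the true
  rise slope exactly, independent of the 10% onset convention.
* rPAT is the median delay from each PPG systolic peak to its nearest
  preceding R-peak; invPAT = 1/rPAT. Records whose ECG clock cannot be
  trusted should set `use_ecg = FALSE`, which falls back to PPG-derived
  heart rate (the per-row `hr_source` column records the channel used).
* The autoencoder featurizer is a 5-layer dense MLP
  (input-128-20-128-input, ReLU, linear output) trained with Adam at step
  size 0.001 on mean-squared error, stopping at a training loss below 0.1
  by default (configurable; the information-content checks in the test
  suite train to 0.001). Hidden widths are this package's choice; depth,
  bottleneck size, activation, step size and stop rule follow the
  convention for this kind of featurizer. Windows are min-max normalized
  to [0, 1]; beat-aligned windows embed physiology rather than phase.

## Audit conventions

* Splits: `no_overlap` partitions patients 80/20, `domain_overlap`
  partitions records, `data_overlap` partitions windows (segment with
  overlapping windows *first* to reproduce the classic leakage). Splits
  are simple random and seeded; stratification is out of scope.
* Leakage is measured on content: shared patients, shared records, and
  window pairs with intersecting sample intervals within a record.
* Two plumbing predictors exist solely to exercise the audits. The ridge
  regression on handcrafted features is the transparent baseline. The
  nearest-neighbour window predictor (label of the closest training
  window under the minimum-over-circular-shifts L2 distance) is the
  minimal *memorizing* predictor: a linear model on four features has no
  capacity to exploit shared samples or patient identity, so the
  leakage-ranking audit — whose entire point is that memorization
  capacity turns leakage into accuracy — uses the nearest-neighbour
  predictor. Neither is a blood-pressure model and neither should be
  quoted for accuracy.
* Calibration: naive predicts the mean of the first three windows' truth;
  offset adds the first window's truth-minus-prediction constant.
  Calibration windows are excluded from evaluation. The calibration unit
  is the record by default; day-scale decay analyses calibrate once per
  patient (`scope = "patient"`) and bin errors by whole days since
  calibration (1-day bins by default; the binning is configurable).
* Error conventions: bias is the mean of prediction-minus-truth, SD is
  the population SD of that error. Device-grading limits (|bias| ≤ 5 and
  SD ≤ 8 mmHg; cumulative |error| fractions 60/85/95, 50/75/90, 40/65/85%
  within 5/10/15 mmHg for grades A–C) are configuration constants with
  inclusive boundaries.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic
cohorts sized for a desk machine: MI oracles at n = 4000; a planted
multi-valued design with 1000 windows; conditioning-dial cohorts of 6
patients × 2 × 240 s (1440 2-s windows); the leakage ranking over 5 seeds
of 20-patient cohorts; calibration decay over 6 patients × 11 daily
records. The exhaustive-oracle equivalence check runs the R-level double
loop on 120-window instances over 5 seeds and both scopes.

## Known limitations

* The WFDB reader covers header + signal pairs in formats 212, 16 and 80
  with channels named PLETH/ABP/ART/ECG-leads — enough for the public ICU
  waveform archives — not the full format zoo; writing WFDB is a
  non-goal.
* Reported multi-valued fractions and Info-Fractions depend on
  reconstruction choices (beat delineation, per-record normalization,
  entropy quantization, k). These are exposed as configuration and should
  be swept when comparing numbers across implementations.
* kNN MI estimates degrade in high dimension; with the 20-dimensional
  autoencoder embedding the mixed estimator remains informative only when
  label classes form tight clusters, which beat-aligned windows
  encourage.
* The per-window latent component in ill mode is white; real confounders
  (vasomotor tone, temperature) are autocorrelated, which would lower the
  *apparent* multi-valued fraction at matched variance.
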