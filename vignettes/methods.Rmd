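---
title: "Methods: from MOS sensor curves to a recall-oriented classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MOS sensor curves to a recall-oriented classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enosedx)
```

This vignette is the package's own account of its science: what is modelled,
which constants are fixed by the instrument and which are design choices,
and what the synthetic cohort can and cannot tell you about clinical data.

## The measurement model

A metal-oxide-semiconductor (MOS) gas sensor changes its surface resistance
when volatile compounds adsorb onto it. Over the calibrated range the
relation between gas concentration $C$ (ppm) and element resistivity $R_s$
is a power law,

$$R_s = A \, C^{\alpha},$$

with per-gas, per-sensor constants. The package ships the constants for the
four Figaro TGS models of a 32-socket array
(`inst/extdata/figaro_calibrations.json`); six sensor/gas combinations have
no published sensitivity curve and are stored as *unavailable* rather than
as zeros, so an accidental use fails loudly (`"no-calibration"`) instead of
silently producing nonsense. Two further entries have $\alpha = 0$ (air and,
on one model, ethanol): the forward model is valid but constant, so the
inversion to ppm raises a typed `"non-invertible"` error which the
featurizer maps to a 0.0 sentinel.

`fit_power_law()` fits $(A, \alpha)$ by ordinary least squares of
$\ln R_s$ on $\ln C$ — the straight-line trendline a spreadsheet fits to a
datasheet plot on log axes. This is deliberate: it reproduces the provenance
of the shipped constants exactly and recovers noiseless generating
parameters to floating-point accuracy, which nonlinear least squares (a
different estimator under multiplicative noise) would not.

### From voltage to resistivity

The instrument digitises a voltage, not a resistance. How that voltage maps
to $R_s$ is not part of the published record, so the package adopts the
standard MOS test circuit: a load divider with
$R_s = R_L (V_{cc} - V_{out}) / V_{out}$, defaults $V_{cc} = 5$ V and
$R_L = 10\,\mathrm{k}\Omega$ (conventional Figaro values), plus a reference
resistance $R_0 = 1\,\mathrm{k}\Omega$ that scales the ohmic result into the
dimensionless units of the calibration tables. All three live in
`divider_circuit()` and belong in run metadata: ppm features are only
comparable between runs that share them. With the defaults, peak voltages
around 1 V give scaled resistivities in the same range as the tables'
$A$ constants (roughly 8–130), which is the consistency argument behind the
$R_0$ default.

## Curve processing and the 32 parameters

An acquisition is 15000 voltage samples per socket. The sampling rate is
fixed by arithmetic: a 120 s horizon over 15000 points forces 125 Hz, with
sample $i$ (0-based) at time $i/125$ and $t = 120$ s mapped to the final
sample (`index = min(round(t * rate), N - 1)`).

Preprocessing is a 5-sample median filter (despiking) followed by a
25-sample centred moving average, both with edge reflection, then
subtraction of the mean of the first second as the baseline offset. These
are minimal, standard choices — the identity of the original filters is
unrecorded — and both windows are arguments of `preprocess()`. At 125 Hz
the 25-sample window spans 0.2 s, far narrower than the tens-of-seconds
response, so peak attenuation is below 1% (asserted in the tests).

From the filtered curve five characteristic points are read: VA (40 s),
VD (60 s), VB = the global maximum (earliest sample on ties), VE (100 s),
VC (120 s). The 32-parameter instance is then:

| block | count | definition |
|---|---|---|
| point voltages | 5 | VA, VB, VC, VD, VE (V) |
| slopes | 7 | AB, BC, AD, DE, EC, BE, DB as $\Delta V / \Delta t$ (V/s) |
| differences | 4 | VB−VA, VB−VC, VB−VD, VB−VE (V) |
| ppm estimates | 7 | inverse power law at the scaled peak resistivity, one per gas |
| statistics | 8 | p75, SD, mode, mean, median, IQR, CV, skewness |
| identifier | 1 | `model_ordinal * 100 + socket` |

Only 11 slope/difference values, 7 ppm values, 8 statistics and the
identifier are explicitly enumerated by the source design — 27 values. The
five raw point voltages are the only completion consistent with a
32-parameter instance, and that reconstruction is the one implemented.

Numerical conventions, all frozen so trained models stay portable:
statistics are computed on the *preprocessed* curve; quantiles use the
linear-interpolation rule; the mode of a continuous signal is the centre of
the fullest 0.01 V histogram bin (lowest bin on ties); CV is guarded to 0
when $|\text{mean}| < 10^{-12}$; skewness is the adjusted Fisher–Pearson
form; a slope whose time gap is below $10^{-9}$ s is 0 with a warning; ppm
estimation uses VB as the representative voltage and sentinels to 0.0
whenever the calibration is unavailable, non-invertible, or VB falls outside
the divider's valid range $(0, V_{cc})$. The feature order of
`feature_names()` is part of the file format.

## Cohort design and leakage control

The redundancy design multiplies each patient into
$\text{containers} \times \text{acquisitions} \times 32$ instances (640 at
the standard 4 × 5 design; 800 files and 25600 instances for a 40-patient
cohort). Redundant instances from one patient are strongly correlated, so
`split_by_patient()` randomises *patients* — stratified by class, seeded,
seed recorded in the split object — and the tests assert the train/test
patient sets are disjoint. How the original 20/20 patient split was chosen
is unrecorded; seeded uniform sampling is this package's choice.

## The classifier

`enose_mlp()` implements a feed-forward network 32 → 64 → 32 → 16 → 2:
z-score input normalization (statistics adapted on training instances only,
constant features passed through unscaled), ReLU hidden layers, softmax
output. The middle hidden width is not pinned down by the source
description beyond "64 down to 16"; geometric halving (64, 32, 16) is the
package's choice and is configurable. Training is mini-batch SGD with
momentum 0.9, initial learning rate 0.001 and inverse-time decay
$lr_t = lr_0 / (1 + 10^{-7} t)$ with $t$ counting parameter updates (the
convention of the legacy SGD optimiser in the framework the architecture
originates from), batch 32, categorical cross-entropy, Glorot-uniform
kernels, zero biases. Per-sample losses are multiplied by
`class_weights[label]`; 1:32 on the cancer class is the recall-oriented
configuration. Epoch shuffling is seeded and the batch remainder is kept as
a short final batch; two runs with the same seed are bitwise identical on
one platform. A non-finite loss aborts with a diagnostic rather than
training through NaNs.

The trainer is written in base R on purpose: the whole optimisation state
(layers, velocities, decay counter) is a few small matrices, and keeping it
inside the package makes the update rule — the part the class-weighting
argument rests on — inspectable and testable. An independent
single-hidden-layer network (`nnet`) cross-checks the separable sanity case
in the test suite.

Evaluation uses a fixed confusion-matrix orientation — rows are the true
label with 0 (HBP) on top, columns the predicted label with 0 on the left,
so false negatives sit lower-left and false positives upper-right — printed
on every report, because "quadrant" descriptions are ambiguous. Accuracy,
per-class precision/recall/F1 and support follow, with zero-denominator
guards. `patient_vote()` (majority per patient, ties to the cancer class to
favour sensitivity) is a clearly-labelled extension: the reference results
are instance-level only.

## What the synthetic cohort is, and is not

`simulate_cohort()` emulates the acquisition *format* and the cohort
*structure*, not MOS adsorption physics. Each curve is

$$v(t) = b + a \,\frac{e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r}}{s_{max}}, \qquad t \ge t_0,$$

a baseline plus a normalised double exponential — the simplest shape with
the observed rise-peak-decay between the fixed sampling times. Defaults:
baseline 0.5 V, peak at 80 ± 2 s, $\tau_r = 25$ s, $\tau_d = 70$ s (placing
the injection near 40 s), sample noise SD 0.01 V, and class-dependent mean
amplitudes 1.0 V (HBP) vs 1.4 V (CaP). Each patient carries an additive
amplitude offset (SD 0.1 V) shared across all of that patient's files — the
feature that makes patient-disjoint splitting a real leakage test — and each
socket a fixed sensitivity gain (0.8–1.2 across the array) so the 32
channels are not clones. Acquisitions are otherwise independent: no
inter-session drift, humidity or temperature confounds, and the class
signal is a single amplitude dimension rather than a cross-sensor odour
pattern.

Consequently, a passing end-to-end test shows the *pipeline* is correct —
featurization preserves a class signal, the split prevents leakage, weighted
training raises minority recall — and says nothing about how well real
urine headspace separates. The clinical headline numbers can only be
reproduced against the real acquisitions, which this package reads but does
not ship.

## Problem sizes and tolerances

The test suite and the acceptance script run the full chain at desk scale —
4 + 4 patients, 2 containers, 2 acquisitions (32 files, 1024 instances,
512 per split side) and 200 epochs — chosen as the smallest design in which
every count of the full study (files per patient, instances per curve,
patients per side) is still exercised with non-trivial multiplicity.
Exact-arithmetic claims (slope/difference definitions, metric identities)
are tested to 1e-12; the calibration round trip and noiseless refit to 1e-9
relative; stochastic claims (noisy refits, class-weighting effects, recall
floors) under fixed seeds at the tolerances stated in the tests.

## Known limitations

- ppm features inherit the invented divider constants; absolute ppm values
  are only meaningful relative to a stated `divider_circuit()`.
- The calibration tables are transcriptions; re-deriving them from
  datasheet graphs is out of scope.
- The generator's independence assumptions (no drift, no covariance between
  gases) are assumptions, stated here rather than hidden.
- Cross-platform bitwise reproducibility of training is not guaranteed;
  same-platform, same-seed runs are.
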