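---
title: "Forecasting impending hypotension: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting impending hypotension: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
computes, which assumptions it makes, which knobs matter, and where the
design was genuinely open.

## The prediction problem

Given minute-by-minute bedside-monitor trends — heart rate (HR, beats/min)
and systolic, diastolic and mean arterial blood pressure (SBP, DBP, MAP,
mmHg) — the task is to decide, at a given minute, whether the patient will
be in a hypotensive episode one to two hours from now, and to estimate the
blood-pressure level over that future half hour. Each labeled example spans
three consecutive intervals:

* an **observation window** (30 or 60 min) providing the features;
* a **gap** (60 or 120 min), the prediction horizon;
* a 30-min **target window** carrying the label or the regression target.

A target window is **hypotensive** when MAP lies strictly between 10 and
60 mmHg for *at least 90%* of its 30 minutes; failing that, it is a
**control** when MAP lies strictly in (10, 200) for *more than 90%*;
otherwise it is excluded. The asymmetric strictness (`>=` for the episode
rule, `>` for the control and validity rules) follows the definitions'
wording exactly and is pinned by boundary tests at 27/30, 26/30 and
57/60. Missing minutes count against both fractions: a window we cannot
see enough of is neither confidently hypotensive nor confidently normal.
The 10/200 bounds are a crude physiologic-plausibility filter, not a
signal-quality index.

Two compilation modes exist. **Multiple** tiles non-overlapping target
windows from minute 0 of each record and keeps every candidate whose
geometry fits, whose observation window passes the validity check (every
series in bounds for more than 95% of the window), and whose target is not
excluded. **Single** draws one example per record, checking for a
hypotensive candidate first and falling back to a uniformly random control
otherwise, so control examples only come from records without a qualifying
episode. The tiling phase is not prescribed by the problem; minute-0
alignment was chosen for reproducibility, and the labeler is exercised at
all phases by an exhaustive-scan oracle test.

## Features (102 per example)

From the four measured series two more are derived: pulse pressure
`PP = SBP − DBP` and relative cardiac output `CO = HR × PP`, the
Windkessel-model proxy that differs from true cardiac output by the
arterial-compliance factor — irrelevant for pattern recognition, which is
scale-free after normalization. Minutes missing any input are missing in
the derived series.

Per series, eight summary statistics: mean, median, SD, variance, IQR,
skewness, kurtosis, and the least-squares slope against the minute index
(units/min). Conventions, chosen once and tested against direct-formula
oracles: population (divide-by-`n`) variance; skewness and kurtosis as
third and fourth standardized central moments (kurtosis not
excess-corrected), both defined as 0 for a constant series (the degenerate
distribution has no shape); IQR from linear-interpolation quantiles.

The 15 zero-lag cross-correlations are the *raw* mean products
`(1/n) Σ x_i y_i` over jointly present minutes — uncentered and
unnormalized by design; the reducer's z-scoring absorbs scale, and the raw
form preserves level-coupling information.

Wavelet features use a 5-level discrete Meyer ("dmey") decomposition. The
62-tap FIR filter pair is inlined as constants; the transform uses
half-sample symmetric boundary extension with repeated reflection, since
the filter is longer than a 30- or 60-sample window. Every level is
therefore boundary-dominated and coefficient vectors grow rather than
shrink — accepted deliberately, because only the *relative* band energies
`Er_b = ‖w_b‖²/Σ‖w_b‖²` are used, which remain well defined, nonnegative
and sum to one (asserted to 1e-9 over thousands of random windows). The
implementation was verified against an independent reference DWT:
approximation coefficients and band energies agree to near machine
precision on frozen test vectors. Gaps are filled before the transform by
linear interpolation with nearest-value edge extension — the observation
validity check bounds missingness at 5%, so imputation perturbs little
while restoring the uniform grid the transform needs. Exact numerical
agreement with any particular historical implementation of the same
decomposition is *not* claimed: boundary handling for filters longer than
the signal is not standardized, so tests assert the normalization
identities and qualitative band behavior (constant series concentrate in
the approximation band; an alternating series in the finest detail band).

Clinical features are age (constant per record, an *a priori* bias) and
the summed doses, in mcg/kg, of blood-pressure-raising
(pressors/inotropes) and -lowering (vasodilators/diuretics/sedatives)
medications delivered during the observation window, with half-open
`[start, end)` membership. The two drug lists are closed; unknown names
fail at parse time rather than silently contributing zero.

## Dimensionality reduction

Features are z-scored with training-set statistics; constant columns
(common for dose features in small sub-samples) are centered and scaled by
1 with a warning rather than producing NaNs. PCA retains the smallest
number of components whose cumulative explained-variance ratio reaches the
target (default 0.90) — a deterministic reading of "approximately 90%".
Loading signs are fixed by making each column's largest-magnitude entry
positive. The reducer is refit for every training-set variant — every fold
and every balanced sub-sample — because normalization and rotation belong
to the training data; whether to refit per sub-sample or once per fold was
genuinely open, and per-sub-sample refit was chosen as the stricter
leakage guard. On the fixture cohorts the retained dimensionality
typically lands in the mid-teens.

## Networks, threshold and early stopping

Both models are feed-forward 3-layer networks, `k → 20 → 1`. The
classifier uses the log-sigmoid in both layers, so its output is a
posterior probability in (0, 1); the regressor uses tanh hidden units with
a linear output for unbounded swing, and standardizes its targets during
training. No installed package provides exactly these topologies with
seeded validation-split early stopping, so training is implemented here:
full-batch Adam (learning rate 0.02) on cross-entropy or MSE, weights
initialized at `N(0, 1/√fan_in)` under the seed, a seeded random 20% of
training rows held out, and early stopping that returns the best-validation
weights once `patience` (default 10) epochs pass without improvement, or at
`max_epochs` (default 500). The identity of optimizer matters less than the
reproducibility contract: same data and seed give identical weights, which
the tests assert. Epoch budget and patience are exposed in
`experiment_config()`.

The decision threshold maximizes `sensitivity(Th) + specificity(Th)` over
candidate thresholds at every distinct training score plus 0 and 1 (a case
is positive when its score is at or above the threshold). Sweeping
candidate scores is exact — between two adjacent scores the confusion
matrix cannot change — which a 0.001-grid oracle test confirms. Ties break
toward the smallest threshold, favoring sensitivity; the wording of the
selection rule does not fix a tie-break, so this choice is documented and
tested rather than assumed. Threshold selection happens per trained model
on its full training rows.

## Evaluation protocol

Cross-validation partitions *records*, not examples: all examples of a
record share its fold, because neighboring windows of one ICU stay are
correlated and splitting them across train and test would inflate
performance. Each classification run balances the training set to 1:1 by
sub-sampling the majority (control) class without replacement — repeated
`n_subsamples` times — while the test fold keeps its natural ~2.5%
prevalence. Regression ignores labels; in multiple mode each run trains on
a random subset of 2,500 examples (all of them in single mode).

Metrics: AUC by the tie-aware rank (Mann–Whitney) statistic, proven
equal to trapezoidal ROC integration by a dual-route test at 1e-10;
accuracy, sensitivity, specificity, PPV and NPV at the selected threshold;
percentage mean absolute error `(100/N) Σ |ŷ_i − y_i|/y_i`; Pearson
correlation; and the slope and intercept of a bisquare-reweighted robust
line of predicted on true MAP (`MASS::rlm`), which a test shows resists a
gross outlier that sways ordinary least squares. With test prevalence `p`,
`PPV = sens·p / (sens·p + (1−spec)(1−p))` — an identity the metric
implementation satisfies exactly, and the arithmetic reason low-prevalence
cohorts pin PPV low no matter how good the discrimination.

Aggregation reports mean ± SD over all fold × sub-sample runs; the
aggregation population (across folds, across sub-samples, or across all
runs) was an open choice, resolved to all-runs and recorded per run in the
report so any other aggregation can be recomputed. Runs whose test fold
lacks one class — impossible at clinical scale, possible in tiny synthetic
cohorts — are flagged, excluded from aggregates, and warned about.

## The synthetic cohort generator

The generator stands in for the ICU database and defines the conditions
every test runs under. Each series is AR(1) noise (coefficient 0.9,
innovation SDs 1.2–1.6) around a per-record baseline (MAP 80, HR 85, PP 45,
jittered across records) with a slow random-walk drift; SBP and DBP derive
from the MAP and PP paths (`SBP = MAP + 2PP/3`, `DBP = SBP − PP`), so the
four pressures are mutually consistent and `SBP ≥ DBP` always. Record
durations are lognormal — skewed like real ICU stays; the cohort default
matches a ~80 h median, while the fixture cohorts use a ~30 h median so a
120-record study runs in minutes. Dropout blocks (2% of minutes, mean
length 8) hit all four series, as monitor disconnections do; artifact
spikes (0.5% per series) inject values outside the 10–200 plausibility
band.

Hypotensive episodes arrive as a Poisson count per record (default 1.1).
Each ramps MAP down over 10 min to a 52 mmHg plateau held for 55 min, then
recovers. The plateau length is the one place the construction must be
exact: for *any* tiling phase, a grid-aligned 30-min window with ≥27
minutes below 60 exists only if the sub-60 stretch lasts at least 54 min,
so the 55-min default guarantees every generated episode yields at least
one hypotensive target window (a cross-module contract test); a 45-min
plateau, though clinically plausible, cannot make that guarantee. Episode
spans are protected from dropout and artifact insertion so the guarantee
survives nonzero noise rates. The episode rate was calibrated once so that
multiple-compilation prevalence on the fixture cohort sits near the ~2.6%
hypotensive-window share characteristic of real ICU trend data, and left
fixed.

The learnable signal is the **precursor signature** imposed on the 120
minutes before each onset: a linear MAP drift (default −0.15 mmHg/min),
pulse-pressure narrowing (default 30% at onset, ramped linearly) and
inflated variability (innovation SDs ×2 at onset). 120 min covers the
observation window of the 30-min/1-h geometry, which makes the task
solvable in principle — and is the knob that makes parameter-recovery
testing meaningful: with strong signatures the cross-validated AUC must
exceed 0.85, and with all three set to zero (the matched null cohort) it
must sit in [0.4, 0.6]. A Monte-Carlo test also recovers the configured
MAP slope from the generated records over the final pre-onset hour. Since
the precursor does not extend past 120 min, the 2-hour-gap geometry sees
little of it; the analysis scripts log (not assert) that AUC at gap 120
does not exceed AUC at gap 60, the expected horizon decay.

What the generator does *not* emulate: mechanistic cardiovascular control,
reflex medication-response dynamics (pressor doses are injected after
onsets as events, influencing only the dose features), realistic artifact
morphology, per-record prevalence heterogeneity, or the marginal
distributions of any real database. Passing the recovery tests therefore
shows the pipeline can find signatures *of the injected kind* at realistic
prevalence and noise — not that real ICU data contains them; conversely
the null-cohort result shows the pipeline does not hallucinate signal
under record-level validation.

## Continuous monitoring

`continuous_predict()` slides the observation window minute by minute: at
prediction time `t` it scores the window ending at `t`, and the outputs
refer to the 30-min target starting at `t + gap`. Minutes whose window is
incomplete or fails the validity check yield an explicit no-prediction
flag with the reason. A consistency test proves the trace at minute `t`
equals the one-off pipeline on the equivalent compiled example. For
plotting against the true MAP, the predicted-MAP series may be shifted
forward by the gap; probabilities are left unshifted to preserve their
predictive reading. The monitor takes a single trained model pair;
averaging the sub-sample ensemble is possible upstream but not built in,
since ensemble handling in this setting has no canonical definition.
Callers choose which models see which record; nothing prevents monitoring
a record the models trained on, and the leakage caveat is the caller's to
honor.

## Problem sizes and numerical notes

The test suite and acceptance analysis use 120-record fixture cohorts
(~30 h records, ~5,400 examples), 3 folds × 3 sub-samples; the full suite
runs in about a minute on one core. Numerical tolerances: wavelet energy
closure 1e-9; statistical-feature oracle agreement 1e-10; AUC dual-route
agreement 1e-10; loading orthonormality 1e-8. Degenerate inputs have
defined behavior throughout: constant series (zero-SD features, skewness
and kurtosis 0), constant regression targets (refused), single-class
training labels (refused), identically zero wavelet input (refused),
constant-true regression scatter (line and correlation reported `NA`).

## Known limitations

* Desk-scale synthetic results are not clinical results; the headline
  numbers here quantify recovery of injected structure only.
* The regression robust-line slope on the fixture cohorts sits well below
  1: with ~97% of targets near the normotensive baseline, the network
  shrinks rare low-MAP predictions toward the bulk. The percentage MAE and
  correlation are the more informative metrics at this scale.
* The wavelet stage's boundary handling dominates 30-sample windows; the
  band energies are self-consistent but not comparable across
  implementations with different extension modes.
* No signal-quality index beyond the 10–200 plausibility band; artifacts
  within bounds pass the filter.
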