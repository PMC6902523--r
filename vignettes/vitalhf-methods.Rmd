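---
title: "Methods: vital-sign representations for perioperative heart-failure risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vital-sign representations for perioperative heart-failure risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vitalhf)
```

## Scope and data model

`vitalhf` classifies perioperative heart-failure risk from five
intraoperative monitoring channels: heart rate, non-invasive systolic and
diastolic blood pressure, SpO2, and pulse pressure (systolic − diastolic,
derived pointwise at exactly matching timestamps by `derive_pp()`).  Series
are kept as irregular timestamped points; no interpolation is ever applied —
pipelines that need fixed windows aggregate by window membership.  Records
missing any of the five channels are flagged incomplete and excluded from
modelling with a logged count rather than silently kept, mirroring the
handling of incompletely monitored cases in the motivating cohort.

## The synthetic cohort: a stated world

The original hospital data cannot be shared, so the generator
(`generator_config()`, `simulate_cohort()`) stands in for it.  Its defaults
are fixed, not tuned: 84 positive and 168 negative patients (the study's
case:control design), 180 minutes of monitoring at one sample per minute (a
typical charted NIBP cadence; the true monitor interval is not
standardised), and adult intraoperative baselines (HR 75 ± 8 bpm, SBP
120 ± 12, DBP 70 ± 8 mmHg, SpO2 98 ± 1 %).  Noise is AR(1) with coefficient
0.8 (stationary marginal variance equal to the stated channel variance) plus
a slow random-walk drift and a shared latent AR(1) factor that correlates
the haemodynamic channels.  Violations of SBP > DBP are resampled and then
clamped; SpO2 is clipped to (0, 100].

The positive-class signature is scaled by one `effect` multiplier and was
chosen so each representation has something to detect: a +8·effect bpm HR
mean shift and ×(1 + effect) HR variance inflation (statistical moments), a
late linear SpO2 decline of 2·effect % over the final third and a
pulse-pressure widening of +10·effect mmHg by end of surgery (SAX shape
words and time–value grid patterns).  The widening is injected through the
systolic channel so `pp = nisysbp − nidiasbp` holds exactly.

What a green test does *not* establish: the generator makes no attempt at
cardiovascular dynamics (no ODE model, no surgical events, no drug
responses), so classifier rankings on synthetic cohorts say nothing about
rankings on real patients.  The tests establish correctness of the
machinery (null calibration at `effect = 0`, signal recovery at
`effect = 2`), not clinical performance.

## Statistical representation

`base_stats()` uses population (1/T) moments with no Bessel correction, and
kurtosis is the raw standardized fourth moment — a normal series scores 3,
not 0.  Percentiles locate rank `(n+1)p` with linear interpolation (R's
type-6 definition), the convention that reproduces the printed quartile
positions `(n+1)/4`, `(n+1)/2`, `3(n+1)/4` exactly.  A zero-variance series
has undefined skewness/kurtosis; both are reported as 0 with a `degenerate`
flag so callers can distinguish a flat channel from a symmetric one.

Each patient yields 18 features per channel (9 statistics × {raw, first
difference}) = 90, named by the underscore convention (`mean_hr`,
`min_diff_hr`, `diff-skew_diff_hr`; the diastolic channel keeps the
historical spelling `nidiasbpe` in feature names).  The source table lists
only 17 names for the pulse-pressure row while the surrounding text counts
90; the regular 18-per-channel grid is implemented.

The "importance 0" feature filter is ambiguous in its source; it is
operationalized (configurably) as Pearson-based: zero-variance columns
(correlation undefined) are dropped, and for any pair with |r| ≥ 0.99 the
later column is dropped, with all removals logged.

## Text representation

The pipeline is: per-channel z-normalization (population σ) → PAA → SAX →
rule engine → LDA.

*PAA*: `paa()` implements the index-based definition (segment *i* averages
points with index in `((N/ω)(i−1), (N/ω)i]`), with fractional boundary
weights when ω ∤ N so the weighted mean is preserved to 1e-12.
`build_corpus()` aggregates by 3-minute time-window membership instead,
which coincides with index-based PAA on a regular grid and degrades
gracefully on irregular sampling; each sample is taken to cover one median
sampling interval, so 180 one-minute samples yield exactly 60 windows and an
8-minute series has only 2 complete windows (too short for a word → the
patient is skipped with a log entry).

*SAX*: the alphabet size is not stated in the source; the default is a = 5
with equiprobable standard-normal breakpoints `qnorm(i/a)` — standard SAX
practice — and configurable.  A value exactly on a breakpoint takes the
upper symbol.

*Rule engine*: the mapping from 3-symbol windows to the phrase vocabulary
`<level> <channel> <modifier> <movement>` is not tabulated in the source, so
the table implemented in `textualize()` is this package's canonical,
versioned definition: movement from the symbol shape (strictly ascending →
`increasing`, descending → `decreasing`, all equal → `steady`, middle
strictly greatest → `peak`, else `varying`); level from the window mean z
against ±0.43 (the standard-normal tertiles); modifier `rapidly`/`slowly`
by whether the absolute net z-change reaches 1σ for monotone movements, and
`upward`/`downward` by the sign of the net change for peak/varying.

*LDA*: each 4-field phrase is a single bag-of-words token.  No LDA package
is available in the target environment, so a collapsed Gibbs sampler is
implemented in C++ (`src/lda_gibbs.cpp`) with symmetric priors α = η = 1/k,
300 sweeps with 100 burn-in, and Rao-Blackwellised θ estimates renormalized
to sum to exactly 1.  k defaults to 5 — the point past which validation
accuracy stopped improving in the motivating experiments.  Topics are
identifiable only up to label permutation; a fixed seed reproduces the fit
exactly because all randomness flows through R's RNG.  Documents
concatenate all five channels in canonical order; a per-indicator document
mode sits behind a flag.  Held-out documents are folded in with frozen
topic-word counts.

## Image representation

`grid_represent()` splits the time axis into n equal columns and the value
axis into m equal rows over per-series bounds, half-open cells with the last
cell of each axis closed so extreme points are counted; bin indices are
computed multiply-first (`floor((x − lo)·k/(hi − lo))`) to avoid float
boundary drift, and a per-point linear-scan oracle verifies exact agreement
in tests.  A constant series degenerates to a single occupied row (row 1) by
convention.  Per-series bounds are the default (each channel grid is a
shape/distribution summary, invariant to level shifts); a fixed-range mode
exists for cross-patient comparability experiments.  Channels fuse in the
fixed order hr, nisysbp, nidiasbp, spo2, pp into a `(5, m, n)` tensor;
m = n = 16 by default — unstated in the source, chosen power-of-two for
clean 2×2 pooling — and each channel is divided by its max cell count
(flag-controlled) for training stability.

The CNN architecture is only constrained to conv/pool/softmax by the
source; the implemented default is deliberately small for a 252-sample
problem: two {3×3 conv (8, then 16 filters), ReLU, 2×2 max-pool} blocks, a
32-unit dense ReLU layer, and a 2-way softmax, trained with Adam (lr 1e-3,
batch 32) on cross-entropy, a stratified 10 % validation split, and early
stopping with patience 10 inside a 50-epoch cap; best-validation weights
are kept and the train/validation loss and accuracy curves are recorded.
With a fixed seed the run is exactly reproducible on a single-threaded
BLAS; multi-threaded BLAS reductions may perturb trailing digits, which is
the documented determinism exception for the CNN backend.

## Classifier suite and evaluation

The target environment ships no CART/boosting/SVM/naive-Bayes/MLP packages,
so the eight reference classifiers are implemented in the package behind
`hf_classifier()`: weighted CART with vectorized split search (gini and
variance criteria) underlies the decision tree, random forest (100 trees,
√p features per split), AdaBoost (SAMME on depth-1 stumps, 100 rounds) and
GBDT (binomial deviance, depth-3 trees, Newton leaf updates, 200 rounds,
shrinkage 0.1); logistic regression is ridge-penalized IRLS (λ = 1/C,
C = 1); Gaussian naive Bayes uses variance smoothing 1e-9; the SVM is an
SMO solver with rbf kernel (γ = 1/(p·var), C = 1) and Platt-scaled
probabilities; the MLP has hidden layers (5, 2), ReLU, and full-batch Adam.
The printed study hyperparameters (estimator counts, kernel, hidden sizes,
split criteria) are the defaults; everything else follows common library
defaults and is echoed into the fitted object.  The SVM, MLP and LR
internally standardize features (stored with the fit) — a package design
choice for numerical robustness on mmHg/bpm scales.

`run_cv()` follows the study protocol: stratified 80/20 split, 10-fold
stratified cross-validation inside the training portion (per-fold metrics
retained, since whether the reported metrics are CV-averaged or test-split
is not stated — both are available), refit on the full training portion,
and a single scoring pass on the held-out 20 %.  The classification
threshold is 0.5 on predicted probability (configurable).  Fold assignment
continues its cycle across classes so fold sizes differ by at most one
while preserving the class ratio within one sample.  `confusion_metrics()`
reports undefined ratios as `NA` with a reason, never silently 0;
`roc_auc()` builds the tie-collapsed step curve and integrates by
trapezoids, which equals the all-pairs rank statistic with ties counted ½
(verified exactly against enumeration in tests).  `benchmark_all()` shares
one outer split across the three representations; the results table has 8
statistical, 8 text and 1 CNN row.  The source's own table prints only 7
statistical and 6 text rows while its text says eight classifiers; the
harness runs all eight for both tabular representations.

The LDA step in `benchmark_all()` is fit unsupervised on all documents
before the split, as in the motivating experiments; topic *features* are
therefore transductive, while the classifier itself never sees test labels.

## Numerical and degenerate-input policy

Zero-variance series: z-normalization is a hard error (caller decides);
statistics report 0 skew/kurt with a flag; corpus construction skips the
patient.  Empty timestamp intersection for pulse pressure is an error.
Probabilities are clamped to [0, 1]; log-losses floor probabilities at
1e-12.  All stochastic components (generator, LDA, classifiers, CNN, CV
splits) draw from R's RNG under explicit seeds, so every artifact can be
reproduced from its JSON provenance sidecar.

## Known limitations

* The generator's realism is a stand-in: no distributional facts about the
  original cohort beyond its counts were available.
* At the default `effect = 1` the statistical representation dominates
  (the mean-shift is trivially captured by `mean_hr`), while the text and
  image representations — which normalize levels away — need stronger
  trend/shape signal (`effect ≈ 2`) to separate reliably at n = 252.
* The CNN is CPU-only and small by design; no transfer learning.
* No hyperparameter search beyond the printed values; no calibration
  analysis; no external validation.
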