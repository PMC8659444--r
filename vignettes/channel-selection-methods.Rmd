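---
title: "Permutation-entropy channel selection for seizure prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-entropy channel selection for seizure prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peselect)
```

## The problem

Scalp EEG for epilepsy monitoring is recorded on a full bipolar montage — 23
derivations in the CHB-MIT layout this package defaults to — but seizure
*prediction* hardware (wearables, implants) wants as few electrodes as
possible, and for a given patient only a few channels typically carry a
pre-seizure signature. `peselect` implements a patient-specific wrapper
selection: summarize each analysis window of each channel by its permutation
entropy, search binary channel masks with a genetic algorithm whose fitness
is cross-validated k-nearest-neighbor accuracy, and then validate the chosen
subset against the full montage with a support vector machine under an
event-level prediction-rate metric.

## Windowing and labeling

Continuous recordings are reduced to labeled 2.8-second windows under a
10-minute seizure prediction horizon (SPH):

* **Pre-ictal**: the horizon `[onset - 10 min, onset)` is tiled with
  non-overlapping windows, anchored at the onset and tiling backward; the
  fractional leftover at the far end is dropped. The window adjacent to the
  onset is the clinically critical one, which is why tiling anchors there
  rather than at the horizon start. A horizon truncated by the start of the
  recording, or by the previous seizure's post-ictal exclusion, still
  contributes its remaining windows — seizures are too scarce to discard.
* **Normal**: one window per clock hour, placed uniformly at random among
  the admissible positions of that hour; admissible means outside every
  `[onset - 10 min, onset + 30 min]` exclusion (SPH plus a 30-minute
  post-ictal recovery). Hours with no admissible position contribute nothing.
* **Class ratio**: the normal class is capped at 10 windows per pre-ictal
  window by uniform subsampling, so accuracy on a test set is not dominated
  by inter-ictal time.
* **Train/test split**: by seizure, chronologically — the earliest seizures
  (with their horizons) train, later ones test, and normal windows are split
  at the first test horizon's start. A predictor must never train on its
  future; published per-patient tables give only train/test seizure counts,
  and the chronological reading is the only leak-free one.

At 256 Hz a 2.8-s window is 716.8 samples; the package uses
`round(2.8 * fs)` = 717 samples and records the choice in every manifest.
Times are seconds from recording start; sample indices are half-open,
0-based internally.

The stated horizon length ("10 min") and window length ("2.8 s") play
different roles: the horizon fixes *labeling*, the window fixes the *unit of
feature extraction*, for both classes. Non-overlapping tiling is used
because the normal-period sampling is defined per window of the same
duration.

## Permutation entropy

Each window and channel is summarized by Bandt–Pompe permutation entropy:
slide an `m`-point delay vector (delay `tau` samples) along the window, map
each vector to the permutation that sorts it ascending, and take the base-2
Shannon entropy of the empirical pattern distribution,

$$PE_M = -\sum_{i=1}^{M!} P_i \log_2 P_i,$$

with probabilities over observed vectors only and `0 log 0 := 0`. Ties are
ranked by order of appearance (stable ranking), the standard convention for
sampled data; it makes the pattern of e.g. `(2, 2, 1)` well defined. PE is
rank-based, hence exactly invariant under strictly monotone amplitude
transforms — amplitude calibration never matters.

Defaults are `m = 3`, `tau = 1`: with 717-sample windows every one of the
`3! = 6` patterns is covered more than 100 times, so the entropy estimate is
essentially unbiased; larger `m` at this window length starts to bias PE
low (the implementation warns when coverage is thin). By default PE is
normalized by `log2(m!)` so white noise scores near 1 and a monotone ramp
scores exactly 0; the raw bits are available with `normalize = FALSE`. The
unnormalized definition and the "near 1 for noise" reading only reconcile
under this normalization, which is why it is the default.

## The synthetic cohort

Real long-term EEG cannot ship with a package, so the generator targets the
*statistical contract* the selector relies on, nothing more physiological:

* background on every channel is iid Gaussian noise (`noise_sd` = 15 µV,
  keeping traces in a realistic ±50 µV display range — irrelevant to
  rank-based PE but convenient for plotting);
* during each pre-seizure horizon, the designated informative channels mix
  in a regular narrowband component:
  `x = (1 - λ) · noise + λ · oscillation`, where the oscillation is a
  sinusoid whose instantaneous frequency random-walks in 3–12 Hz
  (theta/alpha band at 256 Hz). λ (`preictal_regularity`, default 0.8)
  directly manipulates ordinal determinism — exactly the quantity PE
  measures — and class separation is monotone in it (a tested property);
* non-informative channels are statistically identical in both classes, so
  any selector preferring them is wrong by construction.

Everything is reproducible from one integer seed. What passing tests on this
cohort do **not** show: robustness to artifacts, spectral realism, sleep
staging, montage changes, or drifting pre-ictal dynamics — the generator is
a correctness instrument, not a clinical simulator. One spec is one
synthetic "patient"; cohorts are lists of specs with distinct seeds.

Two sampling paths exist. `generate_recording()` plants seizures in a
continuous recording and is exercised through the full windowing pipeline.
`generate_window_set()` draws labeled windows directly from the same two
regimes; it exists because the continuous path yields one normal window per
recording-hour, so a 200-window-per-class study would need ~200 hours of
signal per seed. Selector and classifier studies use the direct path at 200
windows per class; the continuous path is tested at reduced sampling rates
and channel counts.

## The KNN-GA selector

A chromosome is a binary mask over channels (at least one gene on, always —
crossover and mutation repair an all-zero mask by switching one uniformly
chosen gene on). Fitness is stratified 5-fold cross-validated KNN accuracy
(`k = 5`, Euclidean, features standardized per training fold) restricted to
the on-gene columns. Cross-validated rather than resubstitution accuracy is
the only self-consistent choice: resubstitution KNN accuracy at `k = 1` is
degenerately 1.0 for any mask. One fold assignment is drawn per GA run so
all chromosomes compete on identical folds, and fitness is memoized per
mask.

Per generation (population 20, at most 30 generations): fitness →
carry-over of the fittest into the non-bred slots (10% of the population,
i.e. the complement of the 0.9 reproductive fraction, subsuming elitism of
at least one) → fitness-proportionate parent draws (`p_i = f_i / Σf`) for
the bred 90% → uniform crossover (each locus from either parent with
probability ½, crossover probability 1.0) → per-gene mutation at 0.01. The
run stops early when the best fitness has not improved (beyond 1e-12) for 5
generations — a concrete proxy for "the population stops producing
meaningfully different offspring", which is not otherwise operational. An
optional `restarts` argument runs several independent searches and keeps the
best, covering the alternative reading of "30 executions" as multiple runs
rather than 30 generations of one run.

KNN itself is implemented with fully specified tie rules (distance ties →
lower training index; vote ties → the nearest neighbor's class) so that
selection is a pure function of data and seed; library KNN implementations
break ties randomly, which would make fitness non-reproducible.

## SVM validation

The selected subset is validated against the full montage with
C-classification SVMs on the same standardized PE features (the
standardization is part of the fitted model). Three variants are available:

* `lm` — one dual (Lagrange-multiplier) solve at fixed hyperparameters:
  cost 1, RBF width `1/n_features`;
* `evolutionary` — a small (µ+λ) evolution strategy over
  `log2 cost ∈ [-5, 15]`, `log2 γ ∈ [-15, 3]`, 30 candidate evaluations;
* `pso` — a canonical global-best particle swarm over the same box.

Search candidates are scored by stratified CV accuracy *on the training
partition*, and the adopted variant is the one with the best training-CV
score — never the best test score, which would leak the test set into model
choice. Both searches seed the `lm` default point into their initial
population, so their final CV score dominates the fixed default by
construction. Each dual solve is delegated to libsvm (e1071); the package's
contribution is the selection layer, not a re-derivation of SMO.

Window-level results are reported as the four confusion quadrants
(I = pre-ictal hits, II = false alarms, III = misses, IV = normal hits) with
accuracy `(I+IV)/total`, sensitivity `I/(I+III)`, specificity `IV/(II+IV)`.
A zero denominator yields a missing value, never 0 — a printed "0.00"
sensitivity and an undefined one are different facts. The event-level
**prediction rate** is the percentage of test seizures flagged; by default a
seizure counts as predicted when at least one of its horizon windows is
classified pre-ictal (the most permissive consistent rule), with a stricter
majority rule available (`event_rule = "majority"`), and the per-seizure
flags are stored so other thresholds can be recomputed.

## Cohort statistics

`cohort_performance()` ships the per-patient test metrics of the reference
22-patient CHB-MIT cohort (prediction rate, accuracy, sensitivity,
specificity; selected vs all channels; selected channel indices), stored
exactly as printed, with no re-rounding. `summarize_cohort()` recomputes the
cohort comparison: per metric the n/sum/mean/sample-SD of both conditions,
the paired repeated-measures ANOVA (patient as block; with two conditions
its F on (1, n−1) df equals the squared paired t exactly — a tested
identity), and the relative improvement of the selected-channel mean over
the all-channel mean. The SD is the sample (n−1) form: the population form
visibly disagrees with the published per-column values, the sample form
reproduces them, and the same disambiguation selects the repeated-measures
ANOVA over the independent one-way form (which would give F ≈ 1.96 on the
accuracy columns instead of the published 11.56).

Two internal inconsistencies of the reference table are worth knowing.
The stated all-channel mean prediction rate (71.13%) does not equal the mean
of the printed per-patient column (72.65%), and the stated selected-channel
mean (92.42%) does not equal its column mean either (91.51%). The package
always reports what the shipped per-patient values actually imply.
One patient's selected set contains a referential channel outside the
23-channel bipolar montage; it is carried verbatim and excluded from
channel-frequency counts (reported in the `extras` attribute).

## Numerical and scale choices

* Ordinal patterns are indexed lexicographically via the Lehmer code of the
  sorting permutation, computed with O(m²) vectorized comparisons per
  window — no per-vector sorting.
* GA convergence tolerance 1e-12 on the best fitness; all randomness flows
  from explicit integer seeds through a local RNG scope that never perturbs
  the caller's `.Random.seed`.
* EDF input/output supports the continuous 16-bit layout with per-channel
  linear calibration; channel matching to a montage is case- and
  whitespace-insensitive, and duplicate montage labels consume matching file
  channels in file order (the default montage legitimately repeats one
  label).
* Test and acceptance studies use 200 windows per class, 23 channels, 3
  planted informative channels, regularity 0.8, and 10 seeded repetitions —
  the scale at which selector recovery stabilizes (≥ 2 of 3 planted channels
  in at least 8 of 10 runs) while a full run of the suite stays comfortable
  on one CPU.

## Known limitations

* The generator's normal class is stationary white noise; real inter-ictal
  EEG has structure (sleep, artifacts) that can mimic pre-ictal regularity —
  the published per-patient results on real data are *not* reproduced by
  this package and are shipped only as the statistics fixture.
* The event rule underlying the published prediction rates is not
  recoverable from the source material (one patient prints zero sensitivity
  with a 50% prediction rate, impossible under any window-counting rule);
  both implemented rules are explicit and logged per seizure.
* PE with `m = 3` sees only 6 patterns; subtle spectral changes that
  preserve ordinal statistics are invisible to it.
* The GA is a stochastic search: with 23 channels it recovers planted
  subsets reliably but offers no optimality guarantee.
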