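---
title: "Methods: multihead convolutional classification and stepwise EEG channel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multihead convolutional classification and stepwise EEG channel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mhcnet)
```

## The problem

Group-difference EEG studies ask which electrodes — and, by extension,
which cortical regions — carry class-discriminative information, for
example between children with a neurodevelopmental diagnosis and
typically developing controls.  `mhcnet` treats this as a *wrapper*
channel-selection problem: a channel subset is only as good as the
cross-subject classification score a model achieves when restricted to
it.  Everything in the package serves that loop: preprocessing turns
recordings into window stacks, a compact convolutional network (or a
fast surrogate) turns a window stack into a cross-subject f1 score, and
subset search machinery decides which subsets to score.

## Preprocessing

The filter chain is deliberately plain: a 0.5 Hz high-pass removes
electrode drift, a 60 Hz low-pass keeps everything through the low-gamma
band while discarding high-frequency noise, and a 2 Hz-wide notch at
50 Hz suppresses mains interference.  All three are Hamming windowed-sinc
FIR designs (`signal::fir1`); orders follow the usual 3.3/Δf rule from
the transition bandwidths (0.5 Hz for the high-pass, 8 Hz for the
low-pass, 1 Hz for the notch edges), rounded to even so each filter is
linear-phase type I.  Filters are applied forward-backward, so the chain
is zero-phase and waveform timing is preserved — the convention in EEG
toolboxes, where latency structure matters.  The forward-backward pass is
computed by FFT convolution with reflection padding; with transform
lengths covering signal plus kernel this is exact linear convolution, so
it matches direct-form filtering to rounding error while remaining fast
for the long (≈850-tap) high-pass kernel.

Z-scoring is per channel over the whole recording, after filtering and
before windowing.  Per-channel (rather than global) scaling is the
choice that makes channels comparable regardless of electrode impedance
differences; its cost is that *absolute* power differences between
groups are deliberately discarded, so any class contrast must survive as
a *relative* (spectral-shape) difference.  The tests account for this.
A zero-variance channel is an error naming the channel, not a silent
NaN.

Windowing cuts each recording into 2-s windows with 50 % overlap
(S = win_s × sf samples; at 128 Hz, S = 256).  The window count for an
N-sample recording is floor((N − S)/step) + 1 with step = S(1 −
overlap); trailing partial windows are dropped and recordings shorter
than one window contribute nothing — padding would fabricate signal.
An optional amplitude screen (`reject_artifacts`) flags whole 1-s
segments whose peak-to-peak amplitude exceeds a threshold on any
channel; flagged samples exclude any window overlapping them.  It is off
by default and is a simple stand-in occupying the pipeline position
where a full artifact-removal algorithm would run; it makes no claim to
remove ocular or muscular artifacts.

## The classifier

The network is built from **separable 1-D convolutions**: a depthwise
stage convolves each input channel with its own temporal kernel
(learning per-channel time-domain features), and a pointwise stage mixes
channels with 1×1 weights (learning how to combine them).  A separable
layer costs C·K·D + C·D·F + F parameters against C·K·F + F for the full
convolution — the factorisation is what keeps the model small enough to
train on minutes of EEG.

Blocks are arranged in parallel at halving kernel lengths: KL₁ = sf/2,
then sf/4, … down to 2 (six blocks at 128 Hz).  Each block is two
cascading separable layers ("same" padding, ReLU) at its kernel length,
a flattening, and a dense softmax head with one unit per class.  The B
head outputs are averaged element-wise and a final one-unit dense
sigmoid layer produces P(class 1).  The intuition: each branch sees the
window at one temporal scale (half a second down to ~16 ms at 128 Hz),
and the average fuses the scales before the final decision.

Training minimises binary cross-entropy with Adam (β₁ = 0.9,
β₂ = 0.999) over shuffled mini-batches, stopping when the validation
loss has not improved for `patience` epochs and restoring the
best-validation weights.  Training and validation sets must come from
disjoint subjects; the function refuses otherwise.

Defaults: `scl_filters = 8` pointwise filters, `depth_multiplier = 1`,
`head_units = 2`, learning rate 10⁻³, batch 64, ≤50 epochs, patience 5,
dropout off.  The architecture *shape* is the contribution; the widths
are honest defaults exposed in `mhcnet_config()` rather than tuned
constants, and every test that trains a network states its own widths.
The whole network — forward pass, backward pass, Adam — is ~300 lines of
vectorised base R; analytic gradients are verified against central
differences at tolerance 10⁻⁴ in the test suite.  Prediction is
per-window and order-invariant; `predict_labels` assigns class 1 when
P ≥ threshold (ties at the threshold go to class 1, documented
behaviour).

## Channel groups and subset search

The 19-channel 10-20 montage is fixed in a canonical order (frontal
pairs first, midline last) that every matrix, bitmask and tie-break
refers to.  Lobe groups — frontal (7), parietal (5), temporal (2),
occipital (2), central strip (3) — are disjoint and cover the montage;
hemispheres take 8 channels each, leaving Fz, Cz, Pz as midline, in
neither hemisphere.  The anatomical catalogue enumerates 1 + 2 + 5 + 10 +
5 + 19 = 42 groups: the full set, hemispheres, lobes, all C(5,3) = 10
lobe triples, all 5 lobe quadruples (each the complement of one lobe),
and the singletons.  Combination names concatenate lobe letters in the
fixed order F, T, C, P, O.

Exhaustive subset search would need 2¹⁹ − 1 = 524 287 evaluations.
Greedy stepwise search needs p(p+1)/2 = 190: forward selection starts
from the empty set and adds the best-scoring single channel per step;
backward starts from the full set (one evaluation) and removes the least
useful channel per step.  Both produce strictly nested chains covering
every cardinality 1…19, with the best subset per cardinality recorded.
Score ties are broken toward the candidate whose added (or removed)
channel comes earliest in canonical order — greedy search assumes a
unique maximum, and determinism requires a rule.  A scorer returning a
non-finite value aborts the search naming the failing subset.

Two scorers are provided.  `make_model_scorer()` is the full protocol:
each candidate subset is scored by the network's mean f1 over
repeats × folds.  `make_surrogate_scorer()` is the desk-scale surrogate:
log band powers (delta/theta/alpha/beta per channel, periodogram per
2-s window) enter a ridge logistic regression (`glmnet`, α = 0, fixed
λ = 0.01), scored by mean f1 over a seeded subject-level k-fold
cross-validation (k = 4 by default).  Scoring by k-fold rather than a
single holdout matters: with a dozen subjects per class, a single-split
f1 is dominated by which subjects land in the holdout, and the argmax
over 19 candidate channels amplifies that noise; averaging over folds in
which every subject is tested exactly once makes planted-channel
recovery reliable.  The surrogate is explicitly a surrogate — it shares
the wrapper structure and the cross-subject discipline, not the
classifier.

## Evaluation protocol

`make_folds()` assigns *subjects*, never windows: per class, a seeded
permutation is cut into k test blocks (sizes within one when the class
size is not divisible by k; earlier folds take the remainder), and each
fold draws its validation subjects — seeded per fold — from its own
non-test pool.  With 60 subjects per class and k = 10: 6 test, 5
validation, 49 effective-training subjects per class per fold.  Every
run of `evaluate_subset()` asserts the train/validation/test subject
sets are pairwise disjoint.  Metrics (f1, accuracy, precision, recall;
class 1 positive; zero-denominator cases return 0) are computed over the
pooled test windows of each run — windows are the sample unit, which is
also why f1 rather than accuracy is the headline metric when window
counts are class-imbalanced.  The summary over repeats × folds runs
(3 × 10 = 30 by default) reports means, a Student-t confidence interval
on f1 (t rather than normal quantiles: 30 runs is small-sample), and
one-way fixed-effects ANOVA compares f1 across subsets.  ANOVA can be
run on any collection of score groups — all evaluated subsets or only
the per-cardinality bests; both are just lists handed to
`anova_across_subsets()`.

Per-run seeds derive from (master seed, repeat, fold) through a
Lehmer-style integer hash kept below 2³¹, so any single run can be
reproduced in isolation and the whole summary is bit-identical under the
same master seed.

## The synthetic cohort

The generator emulates the *shape* of a two-class paediatric EEG corpus:
two balanced groups (default 60 subjects each), 19 channels, 128 Hz,
minutes-long recordings of variable length (default uniform 60–120 s —
variable deliberately, to exercise unbalanced window counts per
subject).  Each channel is a sum of band-limited Gaussian oscillations
(delta 40, theta 30, alpha 25, beta 10 µV² by default — a plausible
low-frequency-dominant resting profile) plus 1/f background noise
(20 µV² over 1 Hz–Nyquist, slope 1).  Spectra are shaped in the
frequency domain so the expected periodogram equals the target PSD
exactly; per-subject band amplitudes vary log-normally (σ = 0.15),
giving realistic between-subject spread.  The class contrast multiplies
power in one band (theta by default) by (1 + δ) on a designated channel
subset only.  The default contrast band and planted channels are
arbitrary by design: the generator encodes a *controllable*
discriminative structure, not any claim about disorder physiology.

What passing tests therefore show: the pipeline preserves planted
spectral structure, the scorers detect it across subjects, and selection
recovers its carriers at the planted-set rate (and at chance when
δ = 0).  What they do not show: performance on real EEG, whose
artifacts, nonstationarity, volume-conduction correlations between
channels and genuinely unknown effect structure the generator does not
attempt to mimic.

## Numerical and design choices

- **Zero-phase FFT filtering**: reflection padding of kernel length at
  both ends; the |B(f)|² spectrum is applied once (equivalent to
  forward-backward); verified against planted sinusoids (50 Hz ≥ 20 dB
  down, 10 Hz within 5 %).
- **Weight initialisation**: Glorot uniform per tensor, seeded; biases
  zero.
- **Early stopping**: strict improvement threshold 10⁻⁹ on validation
  loss; best weights restored.
- **Fold remainders**: class sizes not divisible by k put one extra test
  subject in each of the first (n mod k) folds.
- **Degenerate inputs**: empty metric input, single-score CI, one-group
  ANOVA, zero-variance channels, too-short windows and subset/montage
  mismatches are all errors with specific messages; all-identical ANOVA
  input returns F = 0, p = 1 rather than 0/0.
- **EDF export**: 16-bit physical/digital scaling per channel, 1-s
  records, whole records only; round-trip error is bounded by half a
  quantisation step (verified in tests; the writer's output was also
  cross-checked against an independent Python EDF reader during
  development).

## Problem sizes used by the test suite

The suite exercises the full protocol at reduced scale, chosen so the
whole run completes in minutes on one CPU while keeping every structural
property intact: network unit tests run at sf = 8–16 Hz with 2–4
filters; the 30-run evaluation protocol runs on a 12-subjects-per-class
cohort at sf = 32 with a width-reduced network; the recovery study runs
the spec conditions it reports — 19 channels, 12 subjects per class,
60-s recordings, δ = 1 theta contrast on three planted channels, the
surrogate scorer, 20 seeded cohorts — plus a δ = 0 control compared
against the 3/19 chance rate by an exact binomial test.  The Monte-Carlo
check of confidence-interval coverage uses 1 500–2 000 replicates of
n = 30.

## Limitations

- The full-network wrapper selection (190 subsets × 30 trainings each)
  is computationally serious at study scale; the package provides the
  machinery and the surrogate, not a precomputed result.  Published
  studies in this area report which cardinalities win with which method,
  and such attributions are protocol- and seed-sensitive; treat any
  single selection trace as one realisation, not the answer.
- The artifact screen is amplitude-only; real ocular/muscular artifact
  removal (ICA, subspace reconstruction) is out of scope.
- No electrode coordinates, topographic interpolation or re-referencing;
  the montage is a fixed label set with anatomical groupings.
- The classifier has no pooling or normalisation layers; with large
  `scl_filters` on long windows the flattened heads grow quickly.
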