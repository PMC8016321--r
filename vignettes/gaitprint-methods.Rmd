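---
title: "Identifying individuals from running gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying individuals from running gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Human gait is individual: a handful of strides is enough to tell one runner
from another. What is much less clear is *where* that individuality lives —
which joint-angle components, which force components, and which parts of the
stance phase carry the information that distinguishes people. `gaitprint`
implements a complete, testable pipeline for that question:

1. build normalized **stride patterns** — 12 stance-phase trajectories (9
   joint-angle components from marker-cluster kinematics, 3 ground-reaction
   force components), each time-normalized to 100 samples and concatenated
   into a 1 × 1200 feature vector;
2. train a **shallow tanh network** (one hidden layer) to assign each stride
   to an individual, training on day-1 strides and evaluating on strides
   recorded on a different day;
3. decompose every correct decision with **layer-wise relevance propagation
   (LRP)** into per-variable relevance, and aggregate those into a group-level
   relevance pattern over the 12 × 100 variables;
4. quantify how much of the identification performance survives when only the
   top-`k` most relevant variables (or whole trajectory subsets) are kept —
   the **relevance-ranked ablation curve**.

Because the package must be verifiable without any participant data, it ships
a **synthetic gait generator** with planted, known discriminative structure.
Every downstream stage is tested against that ground truth.

## The synthetic generator

`synthetic_spec()` + `generate_gait_data()` produce a two-day, multi-subject
cohort. The statistical design:

* **Common templates.** Each of the 12 channels has a fixed population
  template built from a small number of raised-cosine bumps over normalized
  stance phase (angles in degrees, forces in newtons; the vertical GRF is the
  classic double-hump contact curve). The shapes are stylized running curves
  — documented constants, not a validated biomechanical model.
* **Identity signatures.** In the planted channels (by default the five
  frontal/transverse-plane and medio-lateral force channels: hip ab-adduction,
  hip internal-external rotation, knee ab-adduction, ankle in-eversion,
  medio-lateral GRF) each subject's template deviates from the common template
  by a smooth signature: a sum of three raised-cosine bumps supported inside
  the planted window (default: the first 30% of stance), normalized to unit
  RMS over the window, and scaled by `effect_size` × the channel's noise SD.
  Outside the planted channels all subjects share the same template, so the
  ground-truth "identity-carrying" variable set is exactly known
  (`planted_variable_set()`).
* **Trial noise.** Smooth correlated noise (white noise convolved with a
  Gaussian kernel, correlation length 5% of stance duration, unit marginal
  SD), scaled per channel to 5% of the channel's template range. Correlated
  noise is essential: white noise would be erased almost entirely by the
  15 Hz lowpass and make the task artificially easy.
* **Two days.** Trials are split over two recording days; day 2 adds a small
  subject-specific smooth template perturbation (`day2_drift`, default 0.3
  noise SDs) so that the day-2 evaluation is a genuine between-day
  generalization, not a resampling of the training distribution.
* **Cohort size.** The default spec mirrors the emulated study design: 50
  subjects with 29–40 trials in total per subject (at most 20 per day), drawn
  uniformly — class imbalance is present by design. Examples and tests use a
  scaled-down cohort (10 subjects, 30 trials per day) so the whole pipeline
  runs in minutes on one CPU.

### Why `effect_size = 3.2`

`effect_size` is the ratio of between-subject template spread to
within-subject trial noise, per planted channel, and no published per-channel
value exists to copy. The default is *calibrated to reproduce study-like
identifiability*: published single-stride identification accuracies in the
mid-90s% over ~50 individuals correspond to a discriminative-subspace
Mahalanobis separation of roughly d² ≈ 38–40 between individuals. Two
physical constraints shape the calibration. First, the 15 Hz lowpass over a
~0.25 s stance leaves roughly 1–2 resolvable degrees of freedom per channel
inside a 30%-of-stance window, so the planted identity subspace has only ~10
effective dimensions; signature bumps are therefore drawn with widths
0.10–0.14 of stance so their energy sits below the filter cutoff. Spreading
d² ≈ 40 over ~10 dimensions under ideal transfer would need a per-dimension
between/within ratio near 2.5; the full measurement and preprocessing chain
(filtering, resampling, between-day drift, day-split statistics) attenuates
the realized separation further, and 3.2 is the value at which the realized
day-2 separation measured through the complete pipeline matches the target
(synthetic day-2 accuracies then sit in the mid-90s%, as in the emulated
study). The parameter is exposed in the spec for sensitivity analyses.


### Raw mode

`render_raw()` turns a processed trial into measurement-like raw data:
marker clusters (pelvis 4 markers, thigh/shank/foot 3 each, documented
standing geometry) rotated by the forward-composed segment rotations implied
by the angle channels, and the GRF channels embedded in a longer 2400 Hz
record padded with sub-threshold (< 15 N) noise before heel strike and after
toe off. `raw_to_trial()` inverts this with the package's own measurement
chain — force-threshold stance segmentation, rigid-body cluster fits, Z-X-Y
cardan decomposition — and in noise-free mode recovers the generating angle
channels to ~1e-13 degrees, which is the round-trip the kinematics tests
enforce.

## Kinematics

Segment pose is estimated per frame by an orthogonal Procrustes fit of the
marker cluster to its standing-trial position (SVD with a reflection guard;
clusters must have ≥ 3 non-collinear markers). Joint angles are the Z-X-Y
cardan decomposition of the relative rotation `t(R_proximal) %*% R_distal`,
so the standing posture is exactly zero by construction. With the lab axes
(x running direction, y medio-lateral, z vertical), the Y component is
flexion–extension (dorsi-plantarflexion at the ankle), the X component
ab-adduction (in-eversion at the ankle) and the Z component axial rotation
(ab-adduction at the ankle); positive angles follow the right-hand rule about
the lab axes. These sign conventions are package constants; the relevance
analysis is sign-agnostic after standardization. The decomposition errors out
within numerical reach of the gimbal singularity (|middle rotation| → 90°)
instead of returning meaningless triples.

## Preprocessing

* **Stance segmentation** (`detect_stance()`): heel strike and toe off are
  the boundaries of the longest run of vertical GRF ≥ 15 N. A minimum
  contact duration (default 50 ms) rejects threshold-crossing noise spikes —
  the threshold alone is not robust to instrumented-noise flicker. With
  `strict = TRUE` (default) more than one qualifying contact is an error,
  because a valid trial contains exactly one step on the plate. Intervals
  are half-open `[heel_strike, toe_off)`.
* **Filtering** (`lowpass()`): zero-phase 4th-order Butterworth, applied
  forward and backward, with the single-pass cutoff pre-warped so the
  *two-pass* response is −3 dB at the nominal cutoff (15 Hz for angles,
  50 Hz for forces) and ≤ −40 dB at twice the cutoff. The signal mean is
  removed before filtering and restored afterwards, which makes the DC gain
  exactly 1, and the signal is reflection-padded so edge transients stay out
  of the stance window.
* **Time normalization** (`time_normalize()`): shape-preserving monotone
  piecewise-cubic interpolation (PCHIP) onto 100 equally spaced points.
  Endpoints are exact and there is no Runge overshoot on monotone stretches.
  Sample `s` represents the stance interval `[(s−1)%, s%)`; "early stance
  (1–30%)" is samples 1–30.
* **Per-participant standardization** (`standardize_participant()`):
  statistics are computed within participant × day × channel. The default
  subtracts the participant's per-channel *scalar* mean and divides by the
  per-channel *scalar* SD (the RMS of the pointwise across-trial SDs,
  population form). This removes per-participant offset and gain — body
  size, marker placement, absolute force magnitude — *exactly*: adding any
  per-participant affine change to a raw channel reproduces the emitted
  stride patterns to machine precision. It deliberately does **not** remove
  the participant's mean movement shape. The fully pointwise variant
  (`center = "trajectory"`, `sd_mode = "pointwise"`), which subtracts the
  participant's average trajectory sample by sample, is implemented and
  tested; it leaves only stride-to-stride residuals in the features, so
  between-participant template differences — the very thing an
  identification model feeds on, and the very thing the synthetic generator
  plants — do not survive it. We verified this empirically: with pointwise
  centering the network memorizes the training day perfectly and performs at
  chance on the unseen day, for any template-level planted effect. The
  scalar default is therefore the package's considered reading of
  "eliminate body-weight-like effects" that keeps the downstream analysis
  well-posed; the pointwise modes remain available as explicit switches for
  residual-structure studies.
  After participant standardization the features are additionally centred on
  the split-level mean trajectory (per channel and sample, across all trials
  of the day split). This is a dataset-level statistic of already
  participant-invariant values, so the affine invariance is untouched; its
  purpose is to make 0 the genuine "no information" value, which the
  variable-ablation step relies on when it sets excluded features to 0.
  Zero-variance samples are floored at `sd_eps = 1e-8` and flagged.
  Each day is standardized with its own statistics, which mirrors the
  study-design convention of normalizing each dataset per participant; note
  this presupposes known identity at normalization time (the caveat is
  inherited, not second-guessed).
* **Rescaling** (`rescale_unit()`): symmetric division by the maximum
  absolute standardized value. The default scope is *per trial*: each
  trial's 1200-vector is divided by its own maximum, mapping the pattern
  into `[-1, 1]` (zero maps to zero) while preserving the relative
  amplitudes of the channels. The per-channel variant (each channel divided
  by its maximum over the day split) is available as a switch; on centred
  features it inflates channels carrying only stride-to-stride noise to the
  same unit scale as information-bearing channels, which measurably degrades
  the representation (nearest-centroid identification drops by ~20
  percentage points on default synthetic data), so it is not the default.
  The concatenated 1 × 1200 vector (12 trajectories × 100 samples, order
  fixed by `gait_channels()`) is the stride pattern.

## The classifier

A single-hidden-layer network: 1200 linear inputs, tanh hidden layer, linear
outputs with softmax cross-entropy. Hidden size defaults to
`min(2 × features, 60 × classes)` — 2400 for a 50-class cohort, 600 for the
10-class synthetic cohort. Training is mini-batch SGD (batch 25, epoch limit
3000), fixed learning rate 0.02 with classical momentum 0.9, symmetric
uniform fan-in initialization, per-epoch reshuffling with a seeded generator;
runs are bit-reproducible given the seed. The output layer and loss are
package choices (the reference design specifies only the hidden activation);
linear outputs give LRP a well-defined pre-softmax score to decompose. There
is no validation split — training uses all day-1 strides, and stopping is by
the epoch limit plus an optional training-loss plateau rule (relative
improvement < `tol` for `patience` epochs, or loss below `loss_floor`).
Momentum is a pragmatic deviation from plain fixed-rate SGD: it reaches the
same solutions several times faster, and `momentum = 0` restores the plain
variant; every setting is logged in `training` metadata.

Evaluation is **participant-wise**: for participant *p*,
`Accuracy(p) = n_p / N_p × 100`, and the overall figure is the *unweighted*
mean across participants, so a subject with 40 strides counts exactly as
much as one with 20.

## Layer-wise relevance propagation

Relevance starts at the predicted class's pre-softmax score and is
redistributed backwards with the ε-rule,

R_j = Σ_k (a_j w_jk) / (Σ_j′ a_j′ w_j′k + ε·sign(Σ)) · R_k,

with ε = 1e-6 by default; the element-wise tanh is relevance-transparent.
Because the denominators exclude the bias, the rule conserves the score up
to a relative leakage of order ε (biases still shape the forward activations;
relevance attributable to bias-fed activation leaks, which is the standard
ε-rule behaviour). Maps are computed only for correctly classified strides.

Aggregation follows a fixed recipe: normalize each map by its own maximum
absolute value → average element-wise → rectify (absolute value; the
positive-part variant is a config option) → smooth each 100-sample channel
independently with the (0.25, 0.5, 0.25) kernel applied three times
(replicate-edge padding; triple application is the 7-tap binomial
(1,6,15,20,15,6,1)/64, i.e. near-Gaussian) → min–max rescale the full
1200-vector to [0, 1]. Smoothing deliberately does not cross the
concatenation seams between channels: temporal dependence justifies the
smoothing, and it does not hold across seams.

## Relevance-ranked ablation

Variables are sorted by aggregated relevance (ties to the lower index);
for each `k` in a grid anchored at the landmark sizes 16, 200, 500 and 1200,
only the top-`k` variables are kept and every other feature is set to 0 —
which on the standardized, rescaled scale is the participant-mean, i.e. the
"no information" value — and the *unchanged* trained model is re-evaluated.
The retained sets are nested, `k = 1200` reproduces the full evaluation
bit-for-bit, and `k = 0` collapses every stride onto a constant input, so
accuracy drops to chance (100/C %). `channel_subset_accuracy()` does the
same for whole trajectories (e.g. the five planted channels = 500
variables). By default the ranking comes from day-2 correct classifications;
ranking from day-1 relevance is a config choice for testing whether the
ranking itself generalizes.

## Numerical choices and degenerate inputs

* Population-form SDs in standardization (denominator n), so two trials with
  values {+a, −a} standardize exactly to {+1, −1}.
* SD floor `1e-8` with a warning; all-zero channels rescale to zero with a
  warning; a constant aggregated relevance pattern is returned as all-ones
  with a warning (min–max rescaling is undefined there).
* Procrustes fits reject (near-)collinear clusters at a relative
  second-singular-value threshold of 1e-8; reflections are corrected to
  proper rotations.
* Ties in `max.col` prediction break to the lowest class index; ranking ties
  break to the lowest feature index (stable radix order).
* Derived per-trial seeds keep all generation below 2^31 and pure in
  (spec, seed, subject, day, trial).

## Problem sizes used in tests and the acceptance script

Unit tests run on a 4-subject × 6-trials/day cohort with a 240-unit hidden
layer; end-to-end checks use the 10-subject × 30-trials/day cohort with the
1200-600-10 network trained for up to 400 epochs — sizes chosen so the full
suite completes in minutes on a single CPU while the training still reaches
its loss plateau. The permutation-null check trains the same architecture
for 200 epochs on shuffled labels; its chance-level conclusion does not
depend on the epoch budget once the model fits or plateaus.

## What passing tests do and do not show

The generator emulates the *statistical* structure relevant to the analysis:
smooth subject-specific templates, correlated stride-to-stride noise, two-day
structure, trial-count imbalance, native sampling rates, and identity
concentrated in known channels and a known stance window. It does not
emulate soft-tissue artifact, marker occlusion or mislabeling,
foot-strike-type subpopulations, speed variation, fatigue, or any
biomechanically validated coupling between joints — and the planted
signatures are low-dimensional by construction, where real individual
signatures are presumably richer. Passing the planted-recovery tests
therefore shows the *pipeline* is correct (it finds exactly the information
that is there); it does not by itself validate the biomechanical claims on
real runners.

## Known limitations

* The wavelet-based lowpass of the original measurement chain is replaced by
  a Butterworth filter with matched −3 dB semantics; only the cutoff
  contract, not the exact impulse response, is reproduced.
* The segment-frame construction from anatomical calibration is out of
  scope: all rotations are relative to the standing trial, which is exactly
  what the relevance analysis consumes.
* LRP rule and ε are declared package defaults (ε-rule, 1e-6); other
  toolbox rules (α-β) exist and can give different low-level attributions.
* With `center = "trajectory"` the pipeline is faithful to a
  residual-normalization reading but identification on synthetic data is at
  chance by construction; see the standardization section.
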