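# gaitprint

Who is running? `gaitprint` studies the *individuality* of human running
patterns: it builds normalized stride patterns from stance-phase joint-angle
and ground-reaction-force (GRF) trajectories, trains a shallow neural network
to assign each individual stride to the person who produced it, explains
every decision with layer-wise relevance propagation (LRP), and measures
which movement variables and stance time-points actually carry identity
information by re-classifying from relevance-ranked variable subsets.

The package is aimed at biomechanics and movement-science researchers who
want an auditable, fully testable implementation of this analysis — including
a synthetic multi-subject gait generator with *known, planted* discriminative
structure, so every stage can be validated end to end without any
participant data.

## The analysis in brief

**Stride patterns.** For each trial, the stance phase (heel strike to toe
off) is segmented from the vertical GRF with a 15 N threshold. Nine
joint-angle trajectories (hip, knee, ankle × flexion-extension,
ab-adduction, axial rotation; from marker-cluster rigid-body fits against a
standing trial, Z-X-Y cardan decomposition) and three GRF components are
lowpass filtered (zero-phase, −3 dB at 15 / 50 Hz), time-normalized to 100
samples (shape-preserving piecewise cubic), standardized within participant
(removing body-size offset and gain effects), rescaled to [−1, 1], and
concatenated into a 1 × 1200 feature vector:

    x = [angle_1(1..100), ..., angle_9(1..100), GRF_ap, GRF_ml, GRF_v]

**Classifier.** A fully connected 1200–H–C network (tanh hidden layer,
linear outputs, softmax cross-entropy; H = 2400 for a 50-subject cohort,
scaled as `min(2·1200, 60·C)` otherwise) trained with mini-batch SGD
(batch 25, epoch limit 3000) on day-1 strides and evaluated on day-2
strides. Performance is participant-wise accuracy,

    Accuracy(p) = n_p / N_p × 100,

averaged *unweighted* over participants.

**Relevance.** For every correctly classified day-2 stride, LRP (ε-rule)
decomposes the predicted class's pre-softmax score into 1200 signed
per-variable relevances. Maps are normalized to their own maximum, averaged,
rectified, smoothed per channel with a (0.25, 0.5, 0.25) kernel three times,
and min–max rescaled to [0, 1].

**Reduction.** Variables are ranked by aggregated relevance; keeping only
the top-k variables (all others set to 0) and re-evaluating the *unchanged*
model traces out an accuracy-vs-k curve; whole-trajectory subsets (e.g. the
five most relevant channels = 500 variables) are evaluated the same way.

## Worked example

```r
library(gaitprint)
library(dplyr)

# two-day synthetic cohort: 10 subjects, 30 trials/day, identity planted in
# five frontal/transverse-plane + medio-lateral force channels, early stance
spec <- synthetic_spec(n_subjects = 10, trials_per_day = 30, seed = 1)
data <- generate_gait_data(spec)
patterns <- stride_patterns(data)

net <- fit_gait_net(filter(patterns, day == 1), max_epochs = 400, seed = 1)
report <- participant_accuracy(predict(net, filter(patterns, day == 2)))
report
#> <accuracy_report> unweighted mean accuracy 92.33% over 10 participants (300 strides)

maps <- collect_relevance(net, filter(patterns, day == 2))
#> excluding 23 misclassified pattern(s) from relevance analysis
agg <- aggregate_relevance(maps)
summarize_relevance(agg)$by_phase
#> # A tibble: 3 x 3
#>   phase          relevance  share
#>   <chr>              <dbl>  <dbl>
#> 1 early (1-30%)      66.0  0.836
#> 2 mid (31-70%)        7.96 0.101
#> 3 late (71-100%)      4.94 0.0626

curve <- ablation_curve(net, filter(patterns, day == 2), agg)
autoplot(curve)          # accuracy vs number of retained variables
autoplot(agg)            # 12 x 100 relevance heat map
plot_relevance_map(agg, top_k = 200)
```

The mean accuracy (92.33% here) says the network re-identifies most unseen
strides from a different day. The phase split shows the bulk
of the total relevance sits in the first 30% of stance — exactly where
the generator planted the identity signatures — and the ablation curve shows
how quickly accuracy rises as the most relevant variables are added back.
Ground truth is available for checking: `data$truth$planted_variable_set`
holds the planted feature indices, and the top-ranked relevance variables
recover them (see `tests/testthat/test-acceptance.R`).

## Package layout

- `synthetic_spec()`, `generate_gait_data()`, `render_raw()` — synthetic
  cohorts, with raw marker/force rendering for the measurement chain
- `fit_rigid_rotation()`, `cardan_zxy()`, `trial_joint_angles()` — kinematics
- `detect_stance()`, `lowpass()`, `time_normalize()`, `stride_patterns()` —
  preprocessing
- `fit_gait_net()`, `predict()`, `participant_accuracy()` — classification
- `lrp()`, `collect_relevance()`, `aggregate_relevance()`,
  `summarize_relevance()` — relevance
- `rank_variables()`, `mask_patterns()`, `ablation_curve()`,
  `channel_subset_accuracy()` — reduction
- `autoplot()` methods and `tidy()`/`glance()` for every result type

The methods vignette (`vignettes/gaitprint-methods.Rmd`) documents the
models, parameter choices, numerical decisions, and what the synthetic
validation does and does not show.
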