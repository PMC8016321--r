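Package: gaitprint
Title: Identifying Individuals from Running Gait with an Interpretable Shallow Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study the individuality of human running patterns. Builds
    normalized stride patterns (12 stance-phase trajectories of joint angles and
    ground reaction forces, time-normalized to 100 samples and concatenated into a
    1200-dimensional feature vector), trains a shallow tanh network to assign
    strides to individuals, decomposes its decisions with layer-wise relevance
    propagation, and quantifies which movement variables and time points carry
    identity information via relevance-ranked variable ablation. Includes marker
    cluster kinematics (rigid-body pose fitting and Z-X-Y cardan joint angles),
    force-threshold stance segmentation, and a synthetic multi-subject gait
    generator with planted, ground-truth discriminative structure so the full
    pipeline can be validated without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
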