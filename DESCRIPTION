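Package: mhcnet
Title: Multihead Separable-Convolution Networks and Stepwise Channel
    Selection for Cross-Subject EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying which EEG channel subsets and brain
    regions best discriminate two subject classes from multichannel EEG.
    Provides the 19-channel 10-20 montage with its anatomical groupings
    (hemispheres, lobes, lobe combinations, singletons), an FIR filter
    chain with z-score normalisation and overlapping fixed-length
    windowing, a multihead convolutional classifier built from parallel
    blocks of cascading depthwise-separable 1-D convolutions at halving
    kernel lengths, seeded cross-subject k-fold evaluation with f1-based
    summaries (confidence intervals, one-way ANOVA), wrapper-based
    forward and backward stepwise channel selection, and a seeded
    synthetic-EEG cohort generator with class-discriminative band-power
    structure planted on configurable channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
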