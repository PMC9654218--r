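Package: multits
Title: Multi-Kernel Temporal and Spatial Convolution Networks for EEG
    Emotion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the MultiT-S convolutional network for
    electroencephalography (EEG) based emotion classification: a
    four-branch multi-kernel temporal convolution covering 25-200 ms
    receptive fields, depthwise-separable spatial filtering over
    electrodes, and squeeze-and-excitation recalibration of both
    temporal and spatial feature maps.  Ships the comparison
    architectures (Deep ConvNet, Shallow ConvNet, EEGNet) and their
    multi-kernel reforms, analytic trainable-parameter counting and
    frequency-coverage computation, Welch band-power features with
    KNN/random-forest/fully-connected baselines, subject-dependent and
    leave-one-subject-out cross-validation, one-way ANOVA with Dunnett
    many-to-one post hoc comparison, a synthetic labelled-EEG generator
    with band-limited oscillations over 1/f background noise, European
    Data Format import, and a plain-text epoch store.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    mvtnorm,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    class,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'baselines.R'
    'cli.R'
    'convnet_zoo.R'
    'edf.R'
    'epoch_store.R'
    'epoching.R'
    'eval_harness.R'
    'nn_engine.R'
    'spectral.R'
    'stats_compare.R'
    'synthetic.R'
    'train.R'
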