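Package: patchcascade
Title: Patchwise Sampling Strategies for 3D Convolutional Networks on
    Gray-Matter Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how volumetric patch sampling strategies
    affect 3D convolutional neural network classification of structural
    neuroimaging data. Provides a synthetic gray-matter-density cohort
    generator with configurable focal atrophy, the preprocessing tail for
    spatially normalized maps (centered bounding-box crop and FWHM-specified
    Gaussian smoothing), overlapping patch-grid planning with coverage
    auditing for cubic, cuboid and region-of-interest partitions, a
    declarative VGG-like 3D architecture specification with closed-form
    parameter counting and shape propagation plus a compact trainable CNN
    engine, cascaded patch-level/subject-level training with matched
    undersampling and balanced class weights, the five standard evaluation
    indices, repeated-measures ANOVA with Greenhouse-Geisser correction and
    Tukey post hoc tests, a repetition-protocol experiment runner, and
    Monte-Carlo estimation of the mean pairwise distance between points in a
    box.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
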