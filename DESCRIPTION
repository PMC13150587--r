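Package: immobopt
Title: Response-Surface and Machine-Learning Optimization of Enzyme
    Immobilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for design-of-experiments optimization of enzyme
    immobilization on activated supports. Generates three-factor
    Box-Behnken designs, fits the full second-order response-surface
    model by ordinary least squares with a complete adjusted
    (drop-term) ANOVA including lack-of-fit and pure-error
    partitioning and PRESS-based predicted R-squared, and locates
    constrained optima of the fitted surface. Implements
    resampling-plus-uniform-noise data augmentation of replicated
    designs, benchmarking of support vector regression, Gaussian
    process regression and random forest regression with Taylor-diagram
    statistics, and enzyme immobilization metrics: immobilized enzyme
    load, specific activity, immobilization yield, first-order thermal
    deactivation kinetics (inactivation constant, half-life,
    stabilization factor) and reuse-cycle profiles. A synthetic-data
    generator reproduces the statistical structure of replicated
    Box-Behnken immobilization experiments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
Config/testthat/edition: 3
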