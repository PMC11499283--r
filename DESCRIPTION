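Package: tfpulse
Title: Behavioural and Neural Analysis of Temporal-Frequency Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing head-fixed change-detection behaviour and
    brain-wide electrophysiology in a visual temporal-frequency (TF) task.
    Includes synthetic generators for the lognormal 50-ms TF pulse stream,
    trial structure and ground-truth spike populations; a stochastic
    outlier-detection decision agent with censored maximum-likelihood fitting
    and dataset sampling; a leaky-integrator behavioural model with grid
    fitting and reaction-time prediction; psychophysical reverse correlation
    and single/two-pulse lick-probability statistics with a facilitation
    index; a Poisson encoding GLM with temporally unfolded predictors, ridge
    regularisation, nested significance tests, kernel metrics and a focality
    index; model-free unit metrics (pulse PETHs, facilitation, preparatory
    fractions, intrinsic timescales, quality control); and a
    movement and movement-null population-subspace framework with occupancy
    and subpopulation-contribution decompositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    glmnet,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
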