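Package: tracerdiff
Title: Binary Diffusion Coefficients at Infinite Dilution by Classic and
    Machine-Learned Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of binary (tracer) diffusion coefficients at infinite
    dilution, D12, in polar and nonpolar solvents. Implements the classic
    hydrodynamic correlations of Wilke-Chang and Tyn-Calus, the two-parameter
    Stokes-Einstein-type correlation of Magalhaes and co-workers, and the
    hybrid Lennard-Jones model of Zhu and co-workers, together with the
    thermophysical property estimators needed to feed them (molar volume at
    the normal boiling point, the Klincewicz critical-temperature correlation,
    the Lee-Kesler acentric-factor relation, and Lennard-Jones parameter
    estimators). A companion machine-learning pipeline performs collinearity
    based variable selection, min-max scaling, grid-search hyper-parameter
    tuning with k-fold cross validation over five regression algorithms,
    y-randomization validation, and AARD/RMSE/R2 reporting. A synthetic
    database generator emulating the schema of experimental diffusivity
    compilations makes every pipeline stage testable, and a command-line
    program exposes prediction, training, evaluation, y-randomization and
    data generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    ranger,
    xgboost,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
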