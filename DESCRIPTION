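Package: gemyield
Title: Genotype-by-Environment Soybean Yield Prediction with Convolutional
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-environment trial yield prediction and optimal
    genotype-by-environment selection. Provides a synthetic trial-data
    generator with additive genotype/location/year effects, G-by-E
    interaction and window-localised weather responses; preprocessing of
    daily growing-season weather (4-day aggregation, z-score
    normalisation, one-hot encoding, genotype-location-aware data
    splits); two bespoke neural regressors (a multi-branch 1-D CNN and a
    CNN-LSTM hybrid) trained with Adam under an exponential
    learning-rate schedule; a simplex-constrained least-squares model
    ensemble (Generalized Ensemble Method); grouped permutation feature
    importance by RMSE change; and top-k genotype selection with yield
    gap reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
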