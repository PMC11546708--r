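Package: lipidscreen
Title: Lipidomics Biomarker Panel Discovery with Resampled Feature
    Selection and Ensemble Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering blood lipid biomarker panels that
    separate two clinical groups from mass-spectrometry lipidomics
    feature tables. Covers internal-standard relative quantitation,
    quality-control coefficient-of-variation reporting, median plus
    internal-reference-scaling batch normalization, differential
    abundance with fold-change and false-discovery-rate panel filters,
    leave-one-out logistic panel evaluation, an all-relevant Boruta
    shadow-feature selector built on random forests, and a repeated
    leave-group-out cross-validation engine that ranks lipids by
    selection frequency, trains a majority-vote classifier ensemble
    with certainty stratification, and runs signature-size sensitivity
    analysis. A synthetic cohort generator with planted effects and
    closed-form performance oracles makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    glmnet,
    MASS,
    e1071,
    class,
    nnet,
    xgboost,
    nlme
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
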