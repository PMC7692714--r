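Package: cndiag
Title: Compositional Nutrient Diagnosis of Fertigated Banana at Regional and Plot Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tissue-test nutrient diagnosis of fertigated banana
    ('Prata' and 'Cavendish' subgroups) using compositional data analysis.
    Provides centered and isometric log-ratio transforms with sequential
    binary partition balance designs, calibration of regional clr nutrient
    standards from a yield-class confusion matrix (true-negative /
    false-negative partition), Compositional Nutrient Diagnosis (CND)
    indices, nutrient imbalance indices and Mahalanobis distances at the
    regional scale, and closest-successful-neighbor perturbation-vector
    diagnosis at the plot scale. A synthetic observation generator with the
    published distributional structure supports testing and simulation where
    the original farm dataset is unavailable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
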