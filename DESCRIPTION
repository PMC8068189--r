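Package: qsrrisk
Title: QSRR Retention Modelling and Chromatographic Co-Elution De-Risking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for reversed-phase liquid chromatography method
    development driven by quantitative structure retention relationships
    (QSRR). Provides descriptor-matrix pruning and Tanimoto similarity
    characterisation, evolutionary-search wrapper feature selection with
    multiple-linear-regression cross-validated fitness, five retention
    regression algorithms with a leave-3-out external validation protocol,
    two-factor (gradient time by temperature) retention-surface models,
    critical-pair resolution maps with robust centre-point selection, and a
    resolution-coefficient based combinatorial co-elution risk analysis for
    hypothetical mixture components. Includes a synthetic study generator so
    the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    MASS,
    kernlab,
    randomForest,
    mixOmics,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
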