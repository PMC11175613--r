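Package: cognage
Title: Brain Age, Brain Cognition and Their Utility for Explaining Fluid Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates Brain Age as a biomarker for fluid cognition. Builds
    age- and cognition-prediction models from multiple sets of brain features
    via nested 5x5 cross-validated Elastic Net with second-level stacking,
    derives four Brain Age indices (Brain Age, Brain Age Gap, and their
    slope/intercept bias-corrected variants) and Brain Cognition from
    out-of-fold predictions, and partitions the variance in fluid cognition
    into unique and common contributions of chronological age, Brain Age
    indices and Brain Cognition by commonality analysis with hierarchical-
    regression F tests. Includes a linear-Gaussian synthetic cohort generator
    with closed-form ground-truth variance shares so the whole pipeline is
    testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
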