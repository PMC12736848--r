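Package: beadmaze
Title: Force-Based Assessment of Children's Hand Function from Instrumented Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for sensor-based assessment of hand function in
    children. Segments Bead Maze Hand Function Test (BMHFT) trials from triaxial
    force-transducer recordings and scores them by the L1-norm total force;
    computes lift onset, compensatory torque and torque error for a two-digit
    dexterous manipulation task with an off-centre hidden mass; and fits a
    standardized ridge regression of total force on nine sensorimotor and
    demographic features with cross-validated penalty selection, exact linear
    SHAP attributions and Bonferroni-screened Spearman correlations. Includes
    seeded synthetic-data generators that plant detectable events and known
    effect structure so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
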