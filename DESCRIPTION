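Package: morphoscreen
Title: High-Content Morphology Screening for Stromal Cell Function Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell high-content morphology analysis for cultured
    bone-marrow stromal cell (MSC) populations. Generates synthetic
    multi-channel fluorescence fields with ground truth, segments nuclei and
    cells, extracts per-cell morphometry and SER (spot/edge/ridge/...) texture
    features, aggregates per donor, and links morphology to functional
    outcomes (proliferation, osteoblastic and adipocytic differentiation,
    surface-marker expression) via ROUT-filtered Spearman screening,
    group comparison with ROC analysis, and Lasso stability selection with
    per-family error-rate control plus an AIC model ladder.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    glmnet,
    pROC,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
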