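Package: hammettr
Title: Data-Enhanced Hammett Regression for Reaction Barriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust, reference-free estimation of Hammett reaction constants
    (rho) and substituent constants (sigma) by a global Theil-Sen regression
    over all reaction pairs, together with the classic sequential Hammett
    procedure for comparison. Molecular sigma values are decomposed into
    additive per-substituent contributions via categorical (dummy-encoding)
    regression, distance-decay models (power law or exponential), or an
    Axilrod-Teller-Muto three-body variant. A kernel ridge regression layer
    over one-hot composition encodings supports plain and delta machine
    learning with the additive (alpha-) Hammett model as baseline, including
    cross-validated hyperparameter search and learning curves. A synthetic
    data generator with known ground truth enables parameter-recovery tests
    for every fitting stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
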