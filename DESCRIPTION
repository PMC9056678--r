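Package: econf
Title: Electron-Configuration Descriptors and Neural-Network Property
    Prediction for Inorganic Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Composition-based featurization of inorganic compounds: each
    molecular formula is expanded into a signed 118-bit electron-configuration
    vector (one bit per spin-orbital, filled from tabulated ground-state
    configurations by Hund's rule) and used as the input of regression models
    for physicochemical endpoints such as boiling point, melting point,
    pyrolysis point and aqueous solubility. Includes a molecular-formula
    parser with hydrate and nested-group support, dataset curation rules for
    selecting inorganic and organometallic records, a fully connected
    batch-normalized neural network with cross-validated grid search over its
    hyperparameters, support-vector and random-forest baselines, evaluation
    metrics (R squared, mean absolute error, Spearman rank correlation,
    acceptable-prediction counting), and layer-wise principal-component
    analysis of the learned feature space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
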