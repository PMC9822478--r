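Package: macp
Title: Mondrian Aggregated Conformal Prediction for Binary Toxicity
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Class-conditional (Mondrian) inductive conformal prediction for
    imbalanced binary molecular toxicity endpoints, with median aggregation
    across an ensemble of independently calibrated predictors. Covers the
    full modelling chain: SMILES structure standardization (salt stripping,
    stereochemistry removal, organic-element filtering, neutralization,
    tautomer normalization via InChI), physico-chemical descriptor
    calculation through OpenBabel/ChemmineR, stratified
    proper-training/calibration splitting, conformal p-values and prediction
    sets, per-class validity and efficiency metrics with
    sensitivity/specificity/balanced-accuracy reporting, and a synthetic-data
    generator emulating the class structure of acute-toxicity benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
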