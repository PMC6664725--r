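Package: twincnn
Title: Twin Convolutional Networks for Phenotypic Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts normalized IC50 drug response on cancer cell line
    panels from the chemical structure of the drug and the genomic profile
    of the cell line. Drugs enter as canonical SMILES strings encoded into
    symbol-by-position one-hot matrices; cell lines enter as binary vectors
    of mutation states and copy-number alterations. A pair of 1D
    convolutional branches extracts features from each input and a fully
    connected head regresses the normalized log-IC50. The package ships the
    full experimental harness: GDSC-style CSV ingestion and cleansing,
    IC50 normalization, pair/drug-blind/cell-blind/tissue-blind split
    protocols, regression metrics, encoding perturbation studies, learning
    curves, and a seeded synthetic-data generator with a planted
    structure-activity signal so every component is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
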