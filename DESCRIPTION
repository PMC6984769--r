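Package: rpiforest
Title: Sequence-Based Prediction of RNA-Protein Interactions with
    Conjoint Triad and Chaos Game Representation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a protein and an RNA interact from their
    sequences alone. Encodes proteins by conjoint triad frequencies over
    seven physicochemical amino-acid groups (343 features) and by a
    12-gon chaos game representation summarised into 24 segment
    frequencies; encodes RNA by 4-mer frequencies (256 features) and a
    unit-square chaos game representation summarised into 16 cell
    frequencies. Pairs are classified with random forests under 10-fold
    cross-validation with an ntree/mtry grid search, evaluated by
    sensitivity, specificity, accuracy, Matthews correlation and
    ROC/AUC. Also builds positive interaction datasets from PDB
    structures via an atomic contact rule, and generates labelled
    synthetic benchmark pairs with planted sequence motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
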