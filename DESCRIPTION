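Package: cbep
Title: Conformational B-Cell Epitope Prediction from Antigen Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conformational B-cell epitopes from antigen sequences.
    Residues are encoded with five windowed sequence-derived feature classes
    (PSSM evolutionary profile, predicted secondary structure, predicted
    disorder, physicochemical scales, and chain-level dipeptide composition),
    classified as antigenic-determinant residues with a cost-sensitive
    boosting ensemble of support vector machines tuned for the strong class
    imbalance of epitope data, and grouped into candidate epitopes by
    divisive spatial clustering of C-alpha coordinates under a
    distance-derived threshold. Includes parsers for blastpgp PSSM,
    PSIPRED .ss2, DISOPRED and PDB outputs, Fisher-score feature ranking
    with incremental feature selection, leave-one-antigen-out evaluation
    with residue- and epitope-level metrics, and a synthetic antigen
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
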