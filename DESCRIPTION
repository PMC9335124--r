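Package: ngpdbindr
Title: Target-Binding Peptide Discovery from Phage Display Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying target-binding peptides
    from next-generation phage display (NGPD) biopanning experiments. Extracts
    displayed peptides from raw sequencing reads, calls target-enriched
    peptides against control selections using normalized abundance ratios and
    one-tailed Welch t-tests, screens candidate binders against a table of
    known target-unrelated peptides, and removes redundant sequences by greedy
    identity clustering. Candidate binders are encoded with four sequence
    descriptors (amino acid composition, dipeptide composition, pseudo amino
    acid composition, and the composition of k-spaced amino acid group pairs,
    519 dimensions in total), filtered by one of five filter feature-selection
    methods, and classified by an ensemble of ten radial-basis-function
    support vector machines trained on balanced positive/negative
    sub-datasets, with averaging voting over Platt-calibrated probabilities.
    Includes a synthetic-data generator emulating motif-biased binders and
    multinomial round-to-round count enrichment, plus standard
    binary-classifier evaluation metrics (sensitivity, specificity, precision,
    F1, accuracy, Matthews correlation coefficient, AUROC, AUPRC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
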