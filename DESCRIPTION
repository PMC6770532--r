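Package: lncstack
Title: Long Non-Coding RNA Prediction from Global Sequence Features with a
    Stacked Random-Forest Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies transcripts as long non-coding RNA (lncRNA) or
    protein-coding RNA from sequence alone. Extracts a 260-dimension vector
    of global sequence features per transcript (stop-codon statistics,
    Fickett TESTCODE score, open-reading-frame scalars, GC composition,
    k-mer frequencies, CTD distribution descriptors, in-frame hexamer
    score, entropy density profiles, codon-periodicity signal-to-noise
    ratio, and physicochemical properties of the predicted peptide),
    selects optimal feature subsets with a genetic algorithm whose fitness
    is the cross-validated AUC of a random forest, and predicts with a
    two-layer stacked ensemble that averages the scores of ten
    subset-specific random forests. Includes a synthetic transcript
    generator for calibration and testing, evaluation metrics, and a
    command-line interface covering the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
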