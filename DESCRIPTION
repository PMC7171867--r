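Package: bowdti
Title: GPCR-Drug Interaction Prediction from Sequence Wordbooks and
    Fingerprint Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of interactions between G
    protein-coupled receptors (GPCRs) and drug molecules. Receptor
    sequences are encoded with amino acid property scales (AAindex),
    fixed-length encoded fragments are clustered into a learned
    bag-of-words vocabulary (a "wordbook"), and each receptor becomes a
    128-dimensional word-frequency vector. Drugs enter as 256-character
    hexadecimal FP2 fingerprints whose discrete Fourier transform
    amplitudes give a matching 128-dimensional vector. Concatenated
    256-dimensional pair vectors are scored with a distance-weighted
    k-nearest-neighbor classifier, optionally bagged over several
    property scales with randomized neighbor counts and feature
    discard. Includes evaluation tools (ROC/AUC, sensitivity,
    specificity, accuracy, strength, MCC, cross-validation, threshold
    search), classical composition baselines, a synthetic benchmark
    generator with a plantable interaction signal, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
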