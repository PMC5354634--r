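Package: tecpause
Title: Thermodynamic Modeling of RNA Polymerase II Pausing and Backtracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nearest-neighbor basepairing-energy analysis of transcription
    elongation complex (TEC) stability from strand-specific NET-seq 3'-end
    coverage. Scores every transcribed position with the melting-energy
    difference between the RNA:DNA hybrid and the underlying DNA:DNA duplex
    (TEC stability) and with its change upon translocation (delta-TEC), calls
    pause sites as local coverage outliers, benchmarks sequence and nucleosome
    predictors of pausing by ROC/AUC, classifies backtracks from paired
    wild-type and TFIIS-deletion pause sets, and estimates the thermodynamic
    discrimination against transcriptional errors implied by RNA:DNA mismatch
    destabilization. Includes a synthetic NET-seq data generator with planted,
    recoverable structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
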