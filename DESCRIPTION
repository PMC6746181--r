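Package: plasmatrace
Title: Single-Molecule Circulating Tumor DNA Detection, Calibration, and
    Copy-Number Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific circulating tumor DNA (ctDNA)
    analysis from plasma cell-free DNA. Implements unique molecular
    identifier (UMI) consensus calling with library-preparation and
    sequencing error suppression for targeted amplicon resequencing,
    spike-in limit-of-detection calibration with molecule-number
    back-calculation, read-depth downsampling experiments, ultra-low-pass
    whole-genome copy-number profiling with percent-tumor-content and
    percent-genome-altered estimation, and multiregion clonality
    classification with perfect-phylogeny clone trees for bespoke assay
    target selection. A synthetic-data generator with known ground truth
    exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    vcfR
Config/testthat/edition: 3
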