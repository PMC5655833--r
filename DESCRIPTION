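Package: rettomics
Title: DIA Proteome Quantification and Transcriptome-Proteome Integration
    for a Rett-Syndrome Mouse Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A label-free quantification engine for data-independent
    acquisition (DIA) mass spectrometry built on MS2 chromatogram
    area-under-the-curve integration, with retention-time-aware
    normalization, cross-run peptide extraction, and median peptide-to-protein
    roll-up; companions for Cuffdiff-style differential-expression tables,
    CNS cell-type enrichment classification against a reference expression
    matrix, gene-length/direction bias cross-tabulation, and gene-protein
    integration statistics for a MeCP2-deficient (Rett syndrome) mouse
    cortex study design. Ships a synthetic-data generator with recorded
    ground truth so every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
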