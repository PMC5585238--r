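Package: phosphokin
Title: Kinase Activity Inference from TMT Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for finding active kinase candidates in
    drug-resistant cancer cell lines from deep TMT (tandem mass tag)
    phosphoproteomic and phosphotyrosine-proteomic quantification tables.
    Provides readers for MaxQuant-style phosphosite tables and
    kinase-substrate annotation files, class-1 site quality filtering, log2
    median-centering and reference-channel bridging across TMT sets,
    calibration of fold-change cutoffs from duplicate reference channels,
    Welch tests with permutation-based q-values, dual-evidence kinase
    activity calls (kinase-regulatory phosphosites and kinase-substrate
    enrichment analysis), and reconstruction of the activated
    kinase-substrate network.  A synthetic-data module simulates the full
    TMT design with planted ground truth so every stage is testable without
    raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
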