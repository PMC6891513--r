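Package: pepqsar
Title: Peptide Antioxidant QSAR Modelling and Antioxidant Assay Arithmetic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) analysis of
    antioxidant peptides. Encodes variable-length peptide sequences into
    fixed-length descriptor vectors with a two-terminal position numbering
    scheme over a bundled amino-acid property scale, fits partial least
    squares (PLS1, NIPALS) calibration models with leave-one-out Q2
    validation and 2:1 calibration/prediction splitting, and ranks candidate
    peptides by predicted activity. Also implements the closed-form assay
    computations used in cellular antioxidant work: amino-acid class
    composition (hydrophobic, negatively charged, aromatic), ABTS radical
    scavenging percentage, cell viability percentage, cellular antioxidant
    activity (CAA) units from fluorescence-time curves, median-effect EC50
    estimation, and delta-delta-Ct relative expression. Includes synthetic
    generators for peptide-activity datasets with a known descriptor-linear
    signal and fluorescence experiments with a known EC50, so every stage of
    the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
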