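Package: proteopanel
Title: Multi-Layer Proteomic Analysis of Cancer Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-platform proteomic profiling of cell-line
    panels: site-specific glycan quantification by spectral counting of
    glycopeptide-spectrum matches, label-free abundance-matrix preprocessing
    (detection filtering, global-minimum imputation, log2 median normalization,
    replicate collapsing), one-vs-rest Wilcoxon differential expression and
    cosine marker scoring, kinase-substrate enrichment analysis (KSEA) and a
    dual-level kinase-driver screen, mass-spectrometry versus reverse-phase
    protein array (RPPA) concordance analysis, and copy-number to proteome
    cis/trans association. Includes a synthetic-data generator that emulates
    search-engine-level outputs with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
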