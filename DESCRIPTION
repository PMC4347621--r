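Package: mirmodules
Title: Transcription Module Discovery in miRNA Expression Profiles by
    Iterative Signature Biclustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects soft, possibly overlapping transcription modules
    (biclusters) in miRNA read-count matrices with the Iterative Signature
    Algorithm (ISA). Implements the full analysis pipeline used in small
    RNA-seq tumour profiling: library-size filtering, relative-percent
    read-frequency normalization, condensation of miRNAs into sequence
    families, double standardization, ISA with random sparse seeds and
    z-score thresholding, deduplication of fixed points, stability analysis
    across random initializations, consensus matching against external
    biclusterings, and Fisher-exact association of biclusters with sample
    phenotypes. Includes a planted-module synthetic count generator for
    benchmarking recovery without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    pheatmap
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
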