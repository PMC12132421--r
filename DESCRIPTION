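Package: mpramap
Title: Locus-Scale and Degenerate MPRA Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying massively parallel reporter assays (MPRA)
    that tile a genomic locus with barcoded fragments. Implements degenerate
    barcode design and Hamming-distance whitelist error correction,
    barcode-fragment association mapping, depth-normalised log2 enhancer
    activity tracks with trapezoidal AUC scoring and peak calling, a
    saturation-mutagenesis (degenerate MPRA) profiler producing per-position
    mutation effect profiles with Monte-Carlo subsampling, co-expression
    enrichment statistics, and a fully seeded synthetic-data generator so
    every pipeline stage can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    Matrix,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
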