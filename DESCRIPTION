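Package: SisterStrand
Title: Strand-Selection Bias and Host-Gene Relationships of miRNA Sister Pairs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of 5p/3p sister mature microRNA pairs from expression
    microarray data: per-sample log2 expression ratios with sentinel handling
    for alternatively expressed pairs, classification of pairs as alternatively
    (A), mixed (AC) or concurrently (C) expressed relative to a dataset-median
    expression call, and UPGMA clustering of samples and pairs on standardised
    log-ratios. Companion tools annotate intragenic miRNAs by full containment
    of their hairpins in gene spans, correlate intragenic miRNAs with host-gene
    expression under FDR control, and benchmark target-prediction filtering by
    expression anti-correlation, contrasting real miRNA profiles (REAL) with
    host-gene proxy profiles (PROXY) through an observed/expected enrichment
    score over validated interactions. A deterministic synthetic-data generator
    produces annotation, expression and relation inputs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
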