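Package: crossGRN
Title: Cross-Tissue Time-Course Gene Regulatory Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking hepatic transcriptional regulators to
    aortic target genes from two-tissue time-course RNA-seq count data:
    per-timepoint negative-binomial differential expression, Fisher-exact
    pathway enrichment with activation z-scores and time-resolved process
    dynamics, decay-rate (dynGENIE3-style) random-forest network inference
    from liver source genes to aorta target genes with percentile-based edge
    selection, bipartite network assembly, and cross-study directional
    concordance of key regulators. Includes a synthetic two-tissue study
    generator with a planted regulatory network for benchmarking edge
    recovery, and phenotype-level statistics (HOMA-IR, nonparametric group
    tests, quadratic lesion-steatosis fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
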