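Package: dcoexnet
Title: Differential Co-Expression Network Analysis for Two-Class
    Transcriptional Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for contrasting the transcriptional
    wiring of two patient classes: microarray-style preprocessing (log2
    transform, quantile normalization, signal-to-noise probe filtering),
    two-step differential expression against a shared control arm,
    class-specific signed Pearson co-expression networks over the
    differentially expressed genes, hub ("core") gene selection by the
    between-class degree difference statistic, a logistic marker-panel
    builder with ROC/AUC and bootstrap confidence intervals, comparative-Ct
    relative quantification for qPCR validation, and hypergeometric
    gene-set over-representation. Includes a synthetic-data generator with
    planted differential expression and class-specific co-expression
    modules so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    limma,
    optparse
Config/testthat/edition: 3
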