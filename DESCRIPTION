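Package: paradoxcna
Title: Integrative Discovery of Paradoxical Genes from Copy Number and
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-cohort integration of copy number aberration (CNA) calls and
    tumor/normal gene expression to discover "paradoxical" genes, i.e. genes
    whose consensus differential expression is opposite in direction to the
    copy-number status of the region they reside in, and to attribute their
    deregulation to consistently deregulated microRNAs.  Provides heterogeneous
    probe-set integration onto genomic anchors with a per-sample permutation
    test, robust rank aggregation meta-analysis of ranked differential
    expression lists with leave-one-out correction, sample-wise paradox
    validation by randomization, miRNA target-overlap enrichment, CNA-controlled
    miRNA:gene partial correlation with an empirical null, multiple-correlation
    coefficients, and a seeded synthetic multi-cohort generator with planted
    ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
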