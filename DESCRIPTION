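Package: cosq
Title: Lineage-Signature Scoring and Classification of Cervical Tumour
    Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links organoid-derived epithelial lineage signatures to tumour
    classification. Builds squamous-versus-columnar gene signatures from
    probe-level microarrays (quantile normalization, empirical-Bayes
    moderated t-statistics, Benjamini-Hochberg FDR, probe-to-gene collapse),
    scores tumour transcriptomes by the Co-Sq Spearman correlation between
    z-scored expression and signature fold changes with a random-gene-set
    null distribution, derives a stem-cell meta-signature by voting across
    differential-expression tables, and provides the single-cell barcode
    quality-control, log-normalization, highly-variable-gene selection,
    cluster-centroid dendrogram and tissue composition computations used in
    the same workflow. Seeded synthetic-data generators with planted ground
    truth make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    limma,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    ape,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
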