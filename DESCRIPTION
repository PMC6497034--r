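Package: scMixStats
Title: Batch-Mixing Scores, Permutation Tests and QC Rules for Single-Cell
    UMI Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the bespoke statistics used when building a
    multi-sample single-cell transcriptome atlas: rule-based cell and gene
    quality filtration, hemoglobin-high (nucleated red blood cell) cluster
    flagging, a k-nearest-neighbour alignment score that quantifies batch
    mixing in a low-dimensional embedding, cluster-versus-rest marker
    detection by a tie-aware Wilcoxon rank-sum test with expression-fraction
    and fold-change gates, doublet-cluster flagging by shared-marker overlap,
    reference-correlation cluster annotation, permutation tests for the
    concordance of two pseudotime orderings and for multi-way gene-signature
    intersections, and gene-gene co-expression module discovery. A seeded
    negative-binomial UMI-count simulator with planted ground truth (batches,
    cell types, hemoglobin-high cells, doublets, a maturation trajectory and
    signature-gene programs) exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, QualityControl, BatchEffect, Transcriptomics,
    Software
RoxygenNote: 7.3.3
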