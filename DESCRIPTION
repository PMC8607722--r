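Package: scvarmap
Title: Mapping De Novo Loss-of-Function Variant Genes onto Single-Cell
    Brain Transcriptomic Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline that maps curated de novo
    loss-of-function (LOF) variant genes from autism spectrum disorder
    cohorts onto single-cell brain transcriptomic clusters.  Provides a
    graph-based single-cell preprocessing and clustering workflow
    (CPM/log2 normalisation, highly variable gene selection,
    mitochondrial-fraction regression, PCA with an elbow rule,
    shared-nearest-neighbour graphs, Leiden clustering, tSNE), a
    four-test consensus differential-expression caller (Wilcoxon, Welch
    t, bimodal likelihood-ratio, two-part hurdle), exon-level
    mutation-burden constraint scoring ("critical exons") and pLI-based
    constraint enrichment, a generic gene-set overlap engine
    (hypergeometric with sample odds ratios, Bonferroni/BH correction)
    with pathway filters, marker-evidence cell-type annotation,
    spatiotemporal developmental association across 16 brain regions and
    3 periods, and sorted-cell replication via fold change versus
    neurons.  A synthetic-data module generates every input with planted
    ground truth (cell types, markers, constrained exons, high-pLI
    genes, variant-set enrichment, prenatal expression bias) so each
    stage's recovery can be asserted.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    FNN,
    Rtsne,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
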