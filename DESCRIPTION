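Package: aveflow
Title: Transcriptional Identity and Migration Phenotyping of the Anterior
    Visceral Endoderm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterising the anterior visceral
    endoderm (AVE) of the early post-implantation mouse embryo from
    single-cell expression and time-lapse imaging. Provides quality
    control and normalization of Smart-seq2-style count matrices,
    hierarchical cell clustering with Variation-of-Information model
    selection, community-detection sub-clustering with specific-marker
    merging, diffusion pseudotime with smooth-trend differential
    expression, isoform-level chi-squared tests, a ligand-receptor
    communication score over cell-type graphs, bootstrap PCA loading
    significance, proteomics and phosphoproteomics differential analysis
    with kinase-substrate networks, and superpixel mesh-strain motion
    phenotyping of migration videos. A synthetic-data module generates
    negative-binomial count matrices, peptide tables and migration videos
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    igraph,
    limma,
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    methods,
    splines
Suggests:
    testthat (>= 3.0.0),
    withr,
    scran,
    SingleCellExperiment,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
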