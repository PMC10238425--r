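Package: planastra
Title: Spatiotemporal Transcriptomic Reconstruction of Regenerating Planarians
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for building a multi-section spatial
    transcriptomic atlas of regenerating planarians: consensus Louvain
    clustering of single cells with density-based merging and random-forest
    rescue of outliers, rigid serial-section alignment and 3D spatial
    neighbor networks, spot cell-type deconvolution with top-3 co-occurrence
    counting, histology-patch cell-type imputation with pseudo-label
    transfer, hypergeometric enrichment of cell types along the
    anterior-posterior axis, ligand-receptor communication scoring with
    negative-binomial spatial colocalization, and background-matched gene
    module scoring. Ships a synthetic-worm generator with known ground truth
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    MASS,
    randomForest,
    pracma,
    nnet,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
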