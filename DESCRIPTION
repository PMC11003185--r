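Package: cytosupercell
Title: Supercell Aggregation for Large Cytometry Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reduces large flow and mass cytometry datasets by aggregating
    phenotypically similar cells into supercells. Each sample is processed
    independently: a PCA embedding of the arcsinh-transformed marker
    expression is used to build an exact k-nearest-neighbour graph, walktrap
    community detection produces a merge dendrogram, and the dendrogram is
    cut so that the ratio of cells to supercells equals a user-chosen
    granularity parameter gamma. The stored dendrogram can be re-cut at a
    different gamma without recomputing the graph or the walktrap merges.
    Includes deterministic multi-sample orchestration with load balancing,
    mean/median marker aggregation, evaluation metrics (supercell purity,
    adjusted Rand index, normalised mutual information, weighted
    label-transfer accuracy, binned earth mover's distance), downstream
    plumbing for differential expression and abundance analyses
    (majority-vote annotation, pseudobulk matrices, cluster filtering,
    proportion tables), a Gaussian-mixture synthetic data generator, and a
    minimal FCS 3.0/3.1 reader.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    BiocNeighbors,
    BiocParallel,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
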