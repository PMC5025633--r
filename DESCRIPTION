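Package: catens
Title: Ensemble Clustering of Categorical Data via Hamming-Distance Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Consensus clustering for categorical observations (including
    aligned nucleotide sequences). Many hierarchical base clusterings under
    normalized Hamming distance, each cut at a randomly drawn number of
    clusters, are combined through an incidence matrix into an ensembled
    dissimilarity matrix which is then clustered again. A random-subspace
    bootstrap extension handles high-dimensional data, gap-aware integer
    encoding handles aligned sequences, and bootstrap Jaccard resampling
    quantifies cluster stability. A multinomial-mixture generator and a
    full-factorial study runner support systematic evaluation, and a K-modes
    baseline is included for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
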