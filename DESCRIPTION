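Package: jointmds
Title: Joint Multidimensional Scaling for Unsupervised Multi-Modal
    Manifold Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised integration of heterogeneous feature matrices
    (multi-omics, radiomics) by Joint Multidimensional Scaling: weighted
    MDS by SMACOF stress majorization is coupled across domains through
    an entropically regularized Wasserstein-Procrustes matching
    (Sinkhorn transport plan plus orthogonal Procrustes), so that two
    domains are embedded and aligned in one low-dimensional space
    without known sample correspondences. A three-domain extension
    aligns a third modality through successive pairwise rounds against a
    core domain. Includes geodesic (k-nearest-neighbour shortest path)
    dissimilarities, FOSCTTM and k-NN label-transfer evaluation metrics
    with repeated-seed aggregation, Mann-Whitney/Bonferroni and
    variance-to-mean-ratio feature filters, labelled synthetic manifold
    benchmark generators (bifurcation, Swiss roll, circular frustum),
    and a hyperparameter grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
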