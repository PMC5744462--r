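Package: swmclust
Title: Intersubject Clustering and Atlasing of Superficial White Matter Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies reproducible short association (U-fiber) bundles of
    the superficial white matter from multi-subject tractography centroid
    sets. Provides streamline input/output (TRK, TCK and a plain-text
    polyline dialect), the symmetrized maximum corresponding-point distance
    between fibers, sparse-affinity average-link hierarchical clustering
    with adaptive dendrogram partitioning, an intersubject reproducibility
    filter, two-group atlas construction with bagging aggregation,
    automatic anatomical labeling against a cortical parcellation,
    atlas-based segmentation of new subjects with a length-penalized
    distance, and bundle-volume lateralization analysis. A synthetic
    tractogram generator with known ground truth supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
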