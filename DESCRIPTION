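Package: hplus
Title: Scale-Agnostic Discordance Metrics for Internal Cluster Validity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rank-based discordance statistics for evaluating cluster labels
    against a dissimilarity matrix without reference to the scale of the
    dissimilarities. Implements the classical G+ discordance index, its
    balance-unbiased modification H+ (the probability that a within-cluster
    dissimilarity strictly exceeds a between-cluster dissimilarity), exact
    sub-quadratic computation, two quantile-sketch approximation algorithms
    with a guaranteed 1/p error bound, and a stratified bootstrap estimator
    that avoids materialising the full pairwise dissimilarity matrix.
    Includes Gaussian-mixture simulation designs for studying the effect of
    group balance on discordance, and companion validity metrics (adjusted
    Rand index, mean silhouette, within-cluster sums of squares) for
    comparing candidate clusterings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
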