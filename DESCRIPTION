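Package: declust
Title: Differential Gene Expression by Iterative Density-Based Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed genes between two strains
    without fitting a statistical test. Per-gene log expression is
    aggregated into per-strain means and standard deviations, genes are
    split into equal-size batches, and DBSCAN density clustering is run
    per batch in mean space so that density outliers (noise points)
    become the differential calls; genes left in compact clusters pass
    through a second, standard-deviation-based stage that flags genes
    with equal means but diverging within-strain variability. Includes
    five pairwise distance metrics (Euclidean, cityblock, Chebyshev,
    fractional Minkowski, regularized Mahalanobis), a negative-binomial
    two-strain count simulator with planted effects for validation, gene
    set overlap reporting, and scatter-plot rendering of per-batch
    cluster labelings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
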