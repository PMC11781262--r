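Package: superpartition
Title: Scalable Information-Loss-Constrained Feature Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agglomerative feature reduction for wide numeric data sets
    (transcriptomic and epigenomic feature panels) with an explicit,
    user-specified lower bound on the information each reduced feature
    retains about its members. A greedy Partition engine merges the closest
    feature sets only while the intraclass correlation coefficient (or a
    normalized mutual information score) of the merged set stays above the
    information loss criterion, yielding a surjective map from original to
    reduced features. A Gini-constrained single-linkage (minimum spanning
    tree) clustering step first splits large feature sets into size-bounded
    super-clusters, with a k-means fallback for degenerate splits, so the
    engine scales beyond the pairwise-distance memory limit. Includes a
    block-correlated Gaussian simulator with known population intraclass
    correlation for validation, CSV/TSV ingestion, JSON result mapping, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
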