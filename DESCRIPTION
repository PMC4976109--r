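Package: sigdendro
Title: Significant Group Detection in Hierarchical Clustering by Resampling
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects statistically significant groups in agglomerative
    hierarchical clustering. A permutation-based reference distribution of
    dendrogram merge heights is built by independently reshuffling each
    variable (row) of the standardized data matrix, and the observed
    dendrogram is cut at an extreme percentile of that reference so that
    detected clusters carry a significance level alpha = 1 - p/100.
    Includes QQ diagnostics of observed versus expected heights, clustering
    agreement metrics (proportion of wrong clusters, a Cramer's V index and
    an average Jaccard similarity), Beale's pseudo-F comparator for
    selecting the number of clusters, multivariate-normal benchmark data
    generators, and a simulation harness for type-I-error and power studies.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
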