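Package: methylSD
Title: Signal-Detection Analysis of Whole-Genome Bisulfite Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Differential methylation analysis of per-cytosine bisulfite
    counts by signal detection. Control replicates are pooled into a centroid
    reference methylome; per-site Hellinger divergence and total variation
    distance are computed for every sample against it; divergences are
    modeled with a generalized gamma probability distribution, and candidate
    differentially methylated positions (DMPs) above a fitted percentile are
    classified with a learned optimal cutoff. Genes are then tested for
    treatment association with Poisson/negative-binomial likelihood-ratio
    regression on per-sample DMP counts. A Fisher-exact-test baseline
    pipeline, fold-enrichment term analysis, centrality-based network hub
    clustering, and a ground-truth bisulfite count simulator are included so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    MASS,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
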