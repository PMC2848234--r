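Package: exprdeck
Title: Headless Analytics for Expression Matrices: Dynamic Filtering,
    Clustering, Differential Expression and Time-Series Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless toolkit for log-scale expression matrices
    (probes by experiments): a versioned data model with probe lists and
    typed per-probe meta-information; composable boolean filter rules
    yielding dynamic probe lists that track data changes; quality-threshold
    (QT) clustering, k-means, UPGMA/WPGMA and naive plus rapid
    neighbor-joining with silhouette validation and partition comparison;
    differential-expression statistics (t-test, weighted average difference,
    rank product with permutation-based false-positive estimates); stacked
    bin-frequency profile logos; cross-dataset time-shift estimation for
    replicate time courses; and persistent JSON pipelines plus a compressed
    snapshot container for whole analysis states. A synthetic-data generator
    emulates a dense bacterial fermentation time course so every method is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    xml2
Config/testthat/edition: 3
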