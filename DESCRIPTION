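Package: nscl
Title: Nested Semantic Cascade Learning for Hierarchy-Aware Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds label hierarchies from word-embedding semantics or from
    prior-knowledge edge lists, trains multi-class classifiers coarse-to-fine
    as a nested cascade under a combined embedding-regression and
    class-weighted cross-entropy objective, and evaluates predictions with a
    hierarchy-aware mistake-severity metric, hierarchy-ordered confusion
    matrices, and saliency-mask overlap measures (IOU, coverage accuracy,
    coverage precision). Includes a planted-hierarchy synthetic data
    generator so the full pipeline runs offline, and a command-line
    interface for clustering, training, evaluation and experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
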