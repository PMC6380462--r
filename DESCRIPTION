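Package: toxds
Title: Unsupervised Disease-State Discovery from Toxicogenomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers discrete toxin-induced disease states from
    physiology and histopathology profiles of a toxicogenomic cohort and
    characterizes them molecularly. Conditions (compound x dose x time
    point) are normalized to interquartile-range units, embedded with
    consensus t-SNE, weighted by smoothed histopathology severity, and
    clustered by density with a multi-run co-association consensus.
    Called states are profiled by signed log q-value statistics,
    prevalidated elastic-net classification, and gene-set running-sum
    (KS) activity scores; state dynamics are summarized as a transition
    network; and whole-body weight loss is modeled with an Igf1
    latent-factor regression and a stratified Gdf15 regression. A
    synthetic-cohort generator with planted ground truth supports
    recovery and calibration testing throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rtsne,
    glmnet,
    pROC,
    igraph,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
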