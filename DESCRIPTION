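Package: netstrat
Title: Network-Based Stratification of Tumors from Somatic Mutation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies tumor cohorts into molecular subtypes from sparse
    binary somatic mutation profiles. Mutation profiles are smoothed over a
    scored protein-protein interaction network by random walk with restart,
    the most variable smoothed genes are selected and factorized by
    graph-regularized nonnegative matrix factorization under consensus
    clustering with cophenetic model selection, core samples are extracted
    by silhouette width on the consensus distance, subtypes are classified
    by a jackknife-tuned multinomial elastic net yielding per-subtype
    biomarker gene lists, and subtype labels are tested against clinical
    covariates (Kruskal-Wallis, chi-square, Wilcoxon, Kaplan-Meier/log-rank).
    Includes a synthetic cohort generator (planted-partition network,
    subtype driver genes, clinical covariates) so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    survival,
    cluster,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
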