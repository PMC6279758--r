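Package: cafsub
Title: Single-Cell Subtyping of Cancer-Associated Fibroblasts and
    Signature-Based Outcome Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-cell pipeline for
    dissecting cancer-associated fibroblast (CAF) heterogeneity from
    Smart-seq2 plate data and carrying the resulting subtype signatures
    into bulk cohorts.  Covers five-metric quality filtering with an
    outlier-vote exclusion rule, RPKM normalization, spike-in-calibrated
    technical-noise modelling (CV^2 versus mean) and highly-variable-gene
    selection, PCA with repeated lowest-divergence t-SNE and DBSCAN
    population calling, a from-scratch reproducibility-optimized test
    statistic (ROTS) for one-vs-rest differential expression with a
    Wilcoxon cross-check and hypergeometric gene-set over-representation,
    a marker-pair cell-cycle classifier, greedy Spearman compaction of
    differential gene lists into condensed signatures, metagene scoring,
    and conditional logistic regression for matched case-control cohorts.
    A synthetic-data generator reproduces the statistical structure each
    stage assumes so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
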