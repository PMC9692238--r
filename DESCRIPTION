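Package: dasepipe
Title: Population-Level Allele-Specific Expression and cis-Regulatory
    Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting divergent cis-regulation between populations
    from gene-level allele-specific expression (ASE) in F1 hybrid cohorts
    crossed to a common tester. Provides bias-avoiding per-sample SNP filters,
    aggregation of allelic read counts to gene level, log2 ASE ratios, an
    ASE-adapted voom variance model with precision-weighted linear modeling
    and empirical-Bayes moderation, a multivariate adaptive-shrinkage
    meta-analysis across conditions with local false sign rates,
    identity-by-descent classification of sibling plants via a 1-D Gaussian
    mixture, marker-gene projection scores for cell-composition assessment,
    convergence classification between populations with hypergeometric
    overlap tests, and a beta-binomial F1 cohort simulator so that the whole
    pipeline runs on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    limma,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
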