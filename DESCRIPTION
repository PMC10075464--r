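Package: halfsibGP
Title: Genomic Prediction for Half-Sib Hybrid Breeding Trials
Version: 0.1.0
Authors@R:
    person("halfsibGP", "Developers", email = "halfsibgp@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic selection in half-sib hybrid populations
    produced by test-crossing a panel of inbred male lines to a single
    female line. Covers adjustment of replicated phenotypes to best linear
    unbiased estimates under a randomized complete block model, heterosis
    statistics and classification, genotype quality control, LD pruning and
    hybrid genotype deduction, genomic relationship matrices (VanRaden and
    Yang flavours) and epistatic kernels, mixed-linear-model GWAS with a
    polygenic background, marker-assisted selection, kernel BLUP (GBLUP,
    EGBLUP) by REML or Gibbs sampling, BayesB and BayesR whole-genome
    regression, mid-parental covariate models, marker partitioning into
    trait-associated and remaining sets, and a five-scenario repeated
    cross-validation engine with Fisher-z statistics, ANOVA and
    training-set subsampling curves. A synthetic half-sib trial generator
    with known truth makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
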