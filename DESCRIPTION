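Package: metadimorph
Title: Sex Differences in the Serum Metabolome via Pathway Enrichment,
    Gaussian Graphical Models and Stratified mGWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sex-specific differences in population
    metabolomics cohorts. Implements run-day median scaling and log2
    preprocessing, covariate-adjusted single-metabolite association with
    Bonferroni correction and cross-cohort replication, directional pathway
    enrichment via aggregated z-scores, Gaussian graphical model estimation
    (full-order partial correlations conditioned on covariates with
    normal-draw imputation), a cutoff-free network clustering based on
    multiplicative strongest paths with k-means, maximum-spanning-tree
    cluster quality scores and stability diagnostics (silhouette, bootstrap,
    k-robustness), and a sex-stratified metabolite GWAS with an effect
    heterogeneity z-test. A synthetic cohort generator with planted
    correlation modules, sex/age/BMI effects, run-day drift, missingness and
    dimorphic SNP effects provides ground-truth-bearing inputs for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
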