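# metadimorph

Sex-specific differences in the human serum metabolome: covariate-adjusted
association, pathway enrichment, Gaussian-graphical-model network
clustering, and a sex-stratified metabolite GWAS — as a reusable, tested R
package.

## The problem

Men and women differ systematically in the concentrations of a large
fraction of blood metabolites, with consequences for disease risk,
pharmacokinetics and any ambition of sex-aware personalized medicine.
Quantifying those differences in population cohorts raises four linked
statistical tasks, all implemented here:

1. **Single-metabolite association.** For each log2 metabolite
   concentration *y*, fit `y ~ sex + age + BMI` by OLS (sex coded
   female = 1, male = 0, so *β* < 0 means higher in males), with Bonferroni
   control over the panel and sign-consistent replication in an
   independent cohort.
2. **Pathway enrichment via aggregated z-scores.** Standardize each
   metabolite, average the z-scores of a pathway's members per sample, and
   subject that activity to the same regression — a directional test for
   coordinated, one-sided shifts of super-pathways, sub-pathways, or any
   metabolite set.
3. **Data-driven network clustering.** Estimate a Gaussian graphical model
   (full-order partial correlations conditioned on all other metabolites
   plus sex, age, BMI), convert it to a cutoff-free similarity by the
   *multiplicative strongest path*
   `s(i,j) = max over paths of the product of |partial correlations|`,
   cluster the similarity rows with k-means, score each cluster's
   coherence by the mean edge weight of its maximum-weight spanning tree,
   and test each cluster for sex enrichment. Unidentified metabolites —
   invisible to classical pathway analysis — participate fully. Stability
   diagnostics: silhouette over a k grid, sample bootstrap with Jaccard
   matching, and preservation of high-quality clusters across k.
4. **Sex-stratified mGWAS.** Within each stratum, residualize metabolites
   on age, regress on SNP dosages, and test per-SNP effect heterogeneity
   with `z = (β_f − β_m)/sqrt(se_f² + se_m²)`, genome-wide significance at
   `5e-8 / (number of metabolites)`.

Because real cohorts of this type are access-restricted, the package
includes a synthetic cohort generator (`simulate_cohort()`) that plants
correlation modules in the precision matrix, sex/age/BMI effects, run-day
drift, missingness and dimorphic SNP effects — giving every pipeline stage
a ground truth to be tested against. See the methods vignette
(`vignettes/metabolome-dimorphism.Rmd`) for the models, assumptions and
design decisions.

## Worked example

```r
library(metadimorph)

cohort <- simulate_cohort(sim_config(
  n_samples = 500, n_metabolites = 80, n_modules = 4,
  gender_effect_sizes = c("1" = -1, "3" = 0.6), seed = 2024))

logm <- preprocess_cohort(cohort$metabolites)$matrix  # median-scale + log2
scan <- run_association_scan(logm, cohort$covariates)
head(scan[order(scan$p), ], 5)
#>    metabolite_id   beta     se     r2   n        p         direction
#> 2          M0002 -1.166 0.0971 0.2383 465 4.21e-29   higher-in-males
#> 4          M0004 -1.022 0.0954 0.2006 461 4.98e-24   higher-in-males
#> 3          M0003 -1.051 0.1002 0.1900 473 2.86e-23   higher-in-males
#> 1          M0001 -1.018 0.1033 0.1719 472 5.91e-21   higher-in-males
#> 10         M0010  0.645 0.1041 0.0785 455 1.28e-09 higher-in-females
```

The four members of planted module 1 (log2 shift −1, i.e. higher in males)
top the list with betas within sampling error of −1; `r2` is the partial
r² of the sex term and `n` varies because samples missing a metabolite are
dropped. Pathway-level enrichment recovers the planted modules as sets:

```r
enr <- enrich_sets(logm, cohort$covariates,
                   pathway_sets(cohort$annotations, "sub"))
head(enr[order(enr$p), c(1, 2, 4, 7, 8, 10)], 4)
#>         set_id n_members    beta        p signed_log10p significant
#> 7    module_01         4 -0.8849 3.67e-45        44.435        TRUE
#> 9    module_03         4  0.5062 9.92e-16       -15.003        TRUE
#> 3 background_4        10 -0.0242 4.03e-01         0.394       FALSE
#> 6 background_7         7 -0.0225 5.15e-01         0.288       FALSE
```

(`signed_log10p` > 0: higher in males; < 0: higher in females.) The
network route finds the same biology without annotations:

```r
imp <- impute_missing(logm, seed = 2024)       # >90%-missing filter + draws
net <- partial_correlations(imp, cohort$covariates)
spm <- strongest_path_matrix(net)
cl  <- cluster_kmeans(spm, k = 12, seed = 2024)
summ <- summarize_clusters(cl, net, imp, cohort$covariates)
head(summ[order(summ$p), ], 2)
#>   cluster_id size quality    beta        p signed_log10p significant
#> 5  cluster_5    4   0.208 -0.8667 2.17e-46        45.663        TRUE
#> 1  cluster_1    4   0.199  0.4921 1.58e-16       -15.800        TRUE
```

The two enrichment-significant clusters are exactly the two planted
dimorphic modules, with the highest quality scores of the clustering.
`run_pipeline()` chains all stages (plus optional replication and GWAS)
from a YAML config and writes TSV tables and a reproducibility manifest.

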