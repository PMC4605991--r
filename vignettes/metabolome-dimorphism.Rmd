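---
title: "Sex differences in the serum metabolome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex differences in the serum metabolome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`metadimorph` implements a complete workflow for quantifying sex-specific
differences in population-scale serum metabolomics: single-metabolite
association, pathway-level enrichment, a data-driven partial-correlation
network with a cutoff-free clustering, and a sex-stratified metabolite
GWAS. This vignette explains each model, its assumptions, the tunable
parameters, and the design decisions taken where several defensible
choices existed.

## Preprocessing

Raw abundances from multi-batch LC-MS/GC-MS runs drift between measurement
days. `median_scale_by_runday()` divides each metabolite, within each run
day, by its median over the non-missing values, so every metabolite-runday
block ends with median 1. This removes multiplicative instrument drift and
nothing else; no further batch correction or winsorization is applied.
Concentrations are then log2-transformed (`log2_transform()`), because
log-scale metabolite abundances are far closer to normal than raw ones --
`compare_normality()` makes that comparison explicit per metabolite via
Kolmogorov-Smirnov distances to a fitted normal (mean and SD estimated
from the data, i.e. a Lilliefors-style plug-in; we compare the raw KS
*statistics* rather than p-values since the question is which scale is
*closer* to normal, a comparison of distances). Metabolites with fewer
than 10 valid measurements or zero variance are excluded
(`filter_metabolites()`).

Missing values are deliberately left untouched at this stage. Each
downstream analysis has its own, stated policy: regression drops
incomplete samples, the network module imputes.

## Single-metabolite association

For metabolite $j$ with log2 concentration $y_{ij}$ in sample $i$:

$$ y_{ij} = \beta_{0j} + \beta_j\,\mathrm{sex}_i + \gamma_{1j}\,\mathrm{age}_i
   + \gamma_{2j}\,\mathrm{BMI}_i + \varepsilon_{ij} $$

fit by OLS on the samples where $y_{ij}$ is observed (so $N$ varies per
metabolite). Sex is coded **female = 1, male = 0** throughout the package,
so $\beta_j < 0$ means higher concentrations in males. With a dichotomous
regressor this is a covariate-adjusted two-group comparison; under pure
noise its p-values are uniform, which the test suite verifies by
simulation. Family-wise error is controlled by Bonferroni over the number
of metabolites tested ($0.05/507 = 9.86\times10^{-5}$ for a 507-metabolite
panel).

The reported $r^2$ is the **partial** $r^2$ of the sex term,
$t^2/(t^2+\mathrm{df})$ -- the variance explained by sex *given* age and
BMI. A marginal variant is available (`r2 = "marginal"`); the full-model
$r^2$ would conflate the covariates with the effect of interest and is not
offered.

Replication (`compare_cohorts()`) keeps the discovery hits fixed, requires
the same effect sign in the replication cohort, and applies Bonferroni over
the number of discovery-significant metabolites actually measured there.
Metabolites absent from the replication panel are reported `not-measured`
rather than counted as failures.

## Aggregated z-score enrichment

Pathway enrichment uses mean z-score activity: each metabolite is
standardized over its non-missing values (`zscore_matrix()`, sample SD with
the $n-1$ denominator; a population-SD option exists and changes nothing
qualitatively), and a set's per-sample activity is the mean z over its
member metabolites (`set_activity()`). That activity is regressed on sex
with age and BMI exactly as above. The same machinery scores predefined
super-/sub-pathways and the data-driven network clusters, so the two
routes are directly comparable.

Two properties follow from the construction and are encoded as tests:
a singleton set reproduces the single-metabolite p-value exactly (its beta
lives on the z-scale, i.e. divided by the metabolite's observed SD), and
members shifting in *opposite* directions cancel -- the method detects
one-sided, coordinated shifts only. That is intentional: for a sex
contrast the interesting signal is coordinated up- or down-regulation of a
biochemical module. Samples with fewer than half of a set's members
observed (configurable `min_frac`) get a missing activity instead of a
noisy one; this rule is this package's addition to make missing-heavy sets
well-defined. Unannotated metabolites ("unknowns") cannot enter pathway
sets but participate fully in the network route below.

## The Gaussian graphical model

Edges of the network are full-order partial correlations: for metabolites
$i, j$, the correlation that remains after conditioning on *all* other
metabolites plus sex, age and BMI. With precision matrix
$\Omega = \Sigma^{-1}$ of the joint (metabolites + covariates) data,

$$ \rho_{ij\cdot\mathrm{rest}} = -\,\frac{\Omega_{ij}}
   {\sqrt{\Omega_{ii}\,\Omega_{jj}}}. $$

Partial correlations strip out indirect, correlation-chain effects, so the
surviving edges concentrate on direct biochemical relationships. The test
suite checks the precision-matrix formula against the independent
residual-regression definition (regress $i$ and $j$ on everything else,
correlate the residuals) to $10^{-8}$.

Decisions worth stating explicitly:

* **Sex is part of the conditioning set** even though it is also the
  phenotype. The network is meant to capture metabolite-metabolite
  structure net of all measured covariates; sex effects are re-introduced
  afterwards through cluster enrichment.
* **Estimator**: plain sample-covariance inversion. The intended regime is
  $n$ comfortably above $p$ (e.g. 1756 samples for ~500 metabolites); for
  $p \ge n$ experiments a ridge-regularized inverse is available
  (`ridge > 0`), but it is not the default and not used in any headline
  analysis.
* **Missingness policy**: metabolites with more than 90% missing values
  are removed; every remaining missing entry is imputed by an independent
  draw from a normal with the observed mean and SD of that metabolite
  (`impute_missing()`). Unstructured noise can only *dilute* correlations,
  so the induced bias is toward false-negative edges, never false-positive
  ones -- the conservative direction for network inference. Draws are
  unconstrained (they may fall outside the observed range); no truncation
  is applied. Z-scoring before estimation is unnecessary since partial
  correlations are scale-invariant.

## Strongest-path clustering

Hard-thresholding a correlation network before clustering makes every
downstream conclusion depend on the cutoff. The clustering here is
cutoff-free. Let $w_{ij} = |\rho_{ij\cdot\mathrm{rest}}|$. The
*multiplicative strongest path* between two metabolites is the path (over
zero or more intermediates) maximizing the product of edge weights:

$$ s_{ij} = \max_{\text{paths } i \to j} \prod_{(a,b) \in \text{path}} w_{ab},
   \qquad s_{ii} = 1 \text{ (empty product)}. $$

Since all weights lie in $[0,1]$, extending a path can only shrink its
product, so optimal paths are simple and the exact optimum is a Dijkstra
shortest path on $-\log w$ ($s = e^{-d}$); the implementation is verified
against exhaustive simple-path enumeration on random 8-node graphs.
Absolute values are used because a signed product would make "strongest"
ill-defined (two negative edges would outrank a strong positive one);
magnitudes also keep path products monotone. By construction
$s_{ij} \ge w_{ij}$: an indirect route may beat the direct edge, which is
exactly how two metabolites bridged by a shared intermediate end up in the
same cluster.

The rows of $S$ are then feature vectors for standard k-means (Euclidean
metric, 50 random restarts by default, best within-SS solution kept, all
randomness seeded). Using the rows directly is the literal reading of
"k-means on the similarity matrix"; no further transform such as $1-S$ is
applied. The number of clusters is an explicit, ad-hoc analysis parameter
-- 75 for a ~500-metabolite serum panel -- and is *reported against*, not
optimized: `silhouette_evaluation()` scores a grid of k,
`k_robustness()` verifies that high-quality clusters persist across k, and
`bootstrap_stability()` resamples the cohort and reruns the entire network
pipeline, scoring each original cluster by its mean best Jaccard overlap
with the replicate clusters. Jaccard is this package's choice of overlap
statistic; silhouette is reported, never auto-applied.

### Cluster quality

Mean pairwise partial correlation punishes clusters for the inherent
sparsity of a GGM (a chain-like biochemical pathway has many near-zero
pairs). Instead, `cluster_quality()` finds the **maximum-weight spanning
tree** on the cluster's complete subgraph -- the strongest possible
connection visiting every metabolite exactly once -- and scores the cluster
by the arithmetic mean of the tree's edge weights, bounded in $[0,1]$ and
comparable across cluster sizes. A geometric-mean variant is available
behind a flag. Singletons get quality 0 by convention. The implementation
is checked against brute-force enumeration over all spanning trees
(Prüfer-count complete enumeration on small clusters).

Cluster sex enrichment reuses the aggregated z-score regression above, with
Bonferroni over the k clusters. Replication of clusters keeps the
discovery memberships fixed and re-scores them on the replication cohort
(`replicate_clusters()`); the clustering is *not* repeated there.

## Sex-stratified mGWAS

Within each sex stratum, log2 metabolites are residualized on age alone
(`residualize_by_age()`; no BMI or other adjustment, since sex-specific
covariate effects are part of what is being tested), then regressed on
per-SNP allele dosages in $[0,2]$ with an additive model. Metabolites need
at least 250 valid measurements per stratum. The per-stratum estimates are
compared with

$$ z = \frac{\beta_f - \beta_m}{\sqrt{se_f^2 + se_m^2}} \sim
   \mathcal{N}(0,1) \text{ under } H_0 : \beta_f = \beta_m , $$

the standard two-sample heterogeneity statistic: the variance of a
difference of independent estimates is the **sum** of their variances, and
the package deliberately uses the plus sign under the radical (a minus
there is not a valid variance). Genome-wide significance is the
conventional $5\times10^{-8}$ further Bonferroni-corrected for the number
of metabolites tested ($5\times10^{-8}/465 = 1.08\times10^{-10}$ for a
465-metabolite panel). X-chromosome dimorphism analysis is out of scope.
The suite verifies null calibration of $z$ against $\mathcal{N}(0,1)$ on
10,000 null SNP-metabolite pairs and exact recovery of planted female-only
effects.

## The synthetic cohort generator

Real cohort data of this kind are access-restricted, so the package ships
a generator (`simulate_cohort()`) that reproduces the statistical
structure every stage assumes, with known ground truth:

* **Planted modules in the precision matrix.** Log2 concentrations are
  multivariate normal with $\Omega_{ij} = -\rho$ inside each planted
  module and 0 between: every within-module pair has partial correlation
  exactly $\rho$, between-module pairs exactly 0. Planting in the
  precision (not the covariance) makes GGM recovery the natural ground
  truth. Positive definiteness bounds $\rho < 1/(m-1)$ for module size
  $m$; infeasible settings error out with the offending parameters.
* **Defaults as study conditions.** 1000 samples, 300 metabolites, 10
  modules of size 4-6, $\rho = 0.18$ (close to, but inside, the PD bound
  of 0.2 at size 6 -- strong enough that estimated within-module partial
  correlations clear the estimation noise floor of roughly
  $1/\sqrt{n-p}$), two dimorphic modules with log2 shifts $-1$ and $+1$
  (the magnitude of the strongest observed sex differences), age/BMI
  slopes of 0.01 per unit on all metabolites, female fraction 0.514, age
  $\sim\mathcal{N}(60.8, 8.8)$, BMI $\sim\mathcal{N}(28.2, 4.8)$ --
  matching an elderly European population cohort. Four run days with
  log2-scale drift SD 0.2 exercise median scaling; per-metabolite MCAR
  missingness rates are uniform on $[0, 0.1]$.
* **Dimorphic SNPs.** Dosages are binomial(2, MAF) with MAF uniform on
  $[0.1, 0.4]$, no LD. Dimorphic SNPs add $\beta_f = 1.0$ per allele in
  females and 0 in males to one target metabolite each. The effect size
  was fixed by a pre-hoc power calculation: at the metabolite-corrected
  genome-wide threshold the heterogeneity z needs to be ~8 or larger for
  reliable detection, which $\beta_f = 1$ delivers at the cohort sizes
  used. The GWAS harnesses use 1703 samples, the size of a genotyped
  population-cohort subset.
* **Missingness mechanism.** MCAR by default -- an explicit assumption, not
  a claim about LC-MS reality. A left-censoring mode (lowest quantile of
  each metabolite goes missing) is provided because real missingness is
  intensity-dependent; MCAR remains the default because it keeps the
  calibration tests interpretable.
* **Seeding.** One base seed; each random stream (covariates,
  concentrations, run days, missingness, genotypes) uses a fixed documented
  offset from it, so cohorts are bit-reproducible.

What the generator does *not* emulate: peak-level LC-MS artifacts, adduct
ambiguity, retention-time drift, LD structure, population stratification,
or intensity-dependent measurement error. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to every property of real spectrometry data.

## Numerical choices and edge cases

* Ties at the edge-export threshold are kept (`>=` comparison).
* k-means with `k = n` returns singletons without invoking `kmeans()`;
  silhouette at `k = 1` or `k = n` is undefined and reported `NA`.
* Degenerate association designs (a single sex present, zero response
  variance, rank deficiency, fewer than 10 complete cases) are errors, not
  silent fits; scans record them as skipped entries with reasons.
* All-missing metabolite-runday blocks are left unscaled with a warning.
* Bootstrap replicates with singular covariance are skipped and counted.
* Clustering, imputation and bootstrap are deterministic given their seed
  arguments; the pipeline writes every seed into its manifest.

## Problem sizes used in the shipped checks

The test and acceptance harnesses run the full machinery at sizes chosen
to keep a complete run in the minutes range while preserving the regimes
that matter ($n > p$ for the GGM; hundreds of tests for calibration):
10,000 simulated null tests for type-I error, 50 seeds for effect
recovery, 10-50 seeds of the default 300-metabolite configuration for
cluster recovery, 10,000 null SNP-metabolite pairs for GWAS calibration,
and exhaustive-enumeration oracles on graphs of up to 8 nodes, where
enumeration is exact.

## Known limitations

* The z-score enrichment is one-sided by design; antagonistic regulation
  within a set cancels out.
* The unregularized GGM requires $n > p$; the ridge option changes the
  estimand slightly (shrunken partial correlations).
* The quality score's scale depends on the aggregation (arithmetic vs
  geometric mean); only the arithmetic version is used in summaries.
* Replication requires identical metabolite identifiers across cohorts;
  no fuzzy matching of metabolite names is attempted.
* The GWAS module consumes dosage matrices; genotype calling, imputation
  and X-chromosome analyses are out of scope.
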