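#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of [simulate_cohort()]. Defaults
#' describe the study conditions the package's tests operate under: a
#' population cohort with log-normal metabolite abundances whose log-scale
#' precision matrix carries planted equi-partial-correlation modules,
#' additive sex/age/BMI effects, per-run-day instrument drift, missing-at-
#' random dropouts, and SNPs with sex-homogeneous or sex-heterogeneous
#' additive effects.
#'
#' The planted modules are encoded in the precision matrix (not the
#' covariance), so that Gaussian-graphical-model recovery is the natural
#' ground truth: within a module every metabolite pair has partial
#' correlation `within_module_partial_corr`, between modules exactly zero.
#' Positive definiteness requires `within_module_partial_corr <
#' 1/(max module size - 1)`; infeasible settings are rejected with the
#' offending parameters named.
#'
#' @param n_samples,n_metabolites Cohort dimensions.
#' @param n_modules Number of planted correlation blocks.
#' @param module_size_range Integer pair; module sizes are drawn uniformly
#'   from this range. Sizes must sum to at most `n_metabolites`.
#' @param within_module_partial_corr Pairwise partial correlation inside a
#'   module, in (0, 1).
#' @param gender_effect_sizes Named numeric vector mapping module index
#'   (as character) to a log2-scale mean shift added as `effect * gender`
#'   with gender coded female = 1, male = 0 -- so a negative value means
#'   higher concentrations in males.
#' @param age_effect,bmi_effect Log2 shift per year / per BMI unit, applied
#'   to every metabolite (covariate signal downstream models must adjust out).
#' @param female_fraction Probability a sample is female.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions.
#' @param missing_rate_range Per-metabolite missingness rate is drawn
#'   uniformly from this range, in \[0, 1).
#' @param missing_mechanism `"mcar"` (default) or `"left"` (left-censoring:
#'   the lowest quantile of each metabolite goes missing, emulating
#'   intensity-dependent LC-MS dropout).
#' @param n_rundays Number of measurement batches.
#' @param runday_scale_sd SD of the log2-scale multiplicative run-day drift.
#' @param n_snps,n_dimorphic_snps SNP panel size and how many of those have
#'   sex-heterogeneous effects. The remaining SNPs are null.
#' @param maf_range Minor allele frequency range, in (0, 0.5].
#' @param beta_female,beta_male Per-allele log2 effects of each dimorphic
#'   SNP in the two strata.
#' @param unknown_fraction Fraction of non-module metabolites labeled as
#'   unannotated "unknowns" (they enter the network but not pathway sets).
#' @param seed Integer base seed; all random streams derive from it via
#'   fixed offsets (+1 covariates, +2 concentrations, +3 run days,
#'   +4 missingness, +5 genotypes).
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_samples = 200, n_metabolites = 40, n_modules = 3)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_samples = 1000,
                       n_metabolites = 300,
                       n_modules = 10,
                       module_size_range = c(4, 6),
                       within_module_partial_corr = 0.18,
                       gender_effect_sizes = c("1" = -1, "2" = 1),
                       age_effect = 0.01,
                       bmi_effect = 0.01,
                       female_fraction = 0.514,
                       age_mean = 60.8, age_sd = 8.8,
                       bmi_mean = 28.2, bmi_sd = 4.8,
                       missing_rate_range = c(0, 0.1),
                       missing_mechanism = c("mcar", "left"),
                       n_rundays = 4,
                       runday_scale_sd = 0.2,
                       n_snps = 0,
                       n_dimorphic_snps = 0,
                       maf_range = c(0.1, 0.4),
                       beta_female = 1.0,
                       beta_male = 0.0,
                       unknown_fraction = 0.2,
                       seed = 1) {
  cfg <- as.list(environment())
  cfg$missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_samples >= 1, n_metabolites >= 1, n_modules >= 0,
            length(module_size_range) == 2,
            module_size_range[1] <= module_size_range[2],
            module_size_range[1] >= 2,
            within_module_partial_corr > 0, within_module_partial_corr < 1,
            length(missing_rate_range) == 2,
            missing_rate_range[1] <= missing_rate_range[2],
            missing_rate_range[1] >= 0, missing_rate_range[2] < 1,
            n_rundays >= 1, runday_scale_sd >= 0,
            n_snps >= 0, n_dimorphic_snps >= 0, n_dimorphic_snps <= n_snps,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5,
            unknown_fraction >= 0, unknown_fraction <= 1,
            female_fraction > 0, female_fraction < 1)
  if (n_modules * module_size_range[2] > n_metabolites &&
      n_modules * module_size_range[1] > n_metabolites)
    stop("module sizes cannot fit into n_metabolites")
  cfg$seed <- as.integer(seed)
  if (!is.null(cfg$gender_effect_sizes) && length(cfg$gender_effect_sizes) &&
      is.null(names(cfg$gender_effect_sizes)))
    stop("gender_effect_sizes must be named by module index")
  structure(cfg, class = "sim_config")
}

# block precision matrix with planted equi-partial-correlation modules
.planted_precision <- function(p, modules, rho) {
  omega <- diag(p)
  for (mem in modules) omega[mem, mem] <- -rho
  diag(omega) <- 1
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8)
    stop(sprintf(paste0("planted precision matrix is not positive definite: ",
                        "within_module_partial_corr = %.3f with max module ",
                        "size %d (bound: rho < 1/(size-1))"),
                 rho, max(lengths(modules))))
  omega
}

#' Simulate a synthetic metabolomics cohort
#'
#' Draws log2-scale concentrations from a multivariate normal whose precision
#' matrix encodes the planted modules, adds sex/age/BMI (and optional SNP)
#' shifts on the log scale, exponentiates, multiplies by per-run-day scale
#' factors to produce "raw" abundances, and finally applies per-metabolite
#' missingness. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list with elements `metabolites`
#'   ([metabolite_matrix()] of raw abundances with `NA` for missing),
#'   `covariates` (data frame: `gender` female = 1, `age`, `bmi`),
#'   `annotations` (data frame: `metabolite_id`, `super_pathway`,
#'   `sub_pathway`; planted modules appear as sub-pathways, unknowns have
#'   `NA` pathways), `genotypes` (dosage matrix or `NULL`) and `truth`
#'   (planted module memberships, effect sizes, dimorphic SNP table).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  p <- config$n_metabolites

  # --- module layout (deterministic given seed) ---
  set.seed(config$seed + 2L)
  size_choices <- seq(config$module_size_range[1],
                      config$module_size_range[2])
  sizes <- if (config$n_modules == 0) integer(0)
  else if (length(size_choices) == 1)
    rep(size_choices, config$n_modules)
  else sample(size_choices, config$n_modules, replace = TRUE)
  while (sum(sizes) > p) sizes <- sizes[-length(sizes)]
  if (length(sizes) < config$n_modules)
    stop("module sizes sum exceeds n_metabolites")
  bounds <- cumsum(c(0, sizes))
  modules <- lapply(seq_along(sizes),
                    function(k) seq(bounds[k] + 1, bounds[k + 1]))
  omega <- .planted_precision(p, modules, config$within_module_partial_corr)
  sigma <- solve(omega)
  cl <- chol(sigma)
  x <- matrix(stats::rnorm(n * p), n, p) %*% cl

  # --- covariates ---
  set.seed(config$seed + 1L)
  gender <- stats::rbinom(n, 1, config$female_fraction)
  if (length(unique(gender)) < 2 && n >= 2) gender[1:2] <- c(0, 1)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)

  # --- planted effects on the log2 scale ---
  eff <- config$gender_effect_sizes
  for (id in names(eff)) {
    k <- as.integer(id)
    if (k >= 1 && k <= length(modules))
      x[, modules[[k]]] <- x[, modules[[k]]] + eff[[id]] * gender
  }
  x <- x + config$age_effect * (age - config$age_mean)
  x <- x + config$bmi_effect * (bmi - config$bmi_mean)

  # --- genotypes ---
  genotypes <- NULL
  dimorphic <- NULL
  nonmod <- setdiff(seq_len(p), unlist(modules))
  if (config$n_snps > 0) {
    set.seed(config$seed + 5L)
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    genotypes <- vapply(maf, function(q) stats::rbinom(n, 2, q),
                        numeric(n))
    colnames(genotypes) <- sprintf("rs%05d", seq_len(config$n_snps))
    if (config$n_dimorphic_snps > 0) {
      tgt <- if (length(nonmod) >= config$n_dimorphic_snps)
        nonmod[seq_len(config$n_dimorphic_snps)]
      else seq_len(config$n_dimorphic_snps)
      dimorphic <- data.frame(
        snp_id = colnames(genotypes)[seq_len(config$n_dimorphic_snps)],
        metabolite_index = tgt,
        beta_female = config$beta_female,
        beta_male = config$beta_male,
        stringsAsFactors = FALSE)
      for (j in seq_len(config$n_dimorphic_snps)) {
        per_allele <- config$beta_female * gender +
          config$beta_male * (1 - gender)
        x[, tgt[j]] <- x[, tgt[j]] + genotypes[, j] * per_allele
      }
    }
  }

  # --- run-day drift, exponentiation ---
  set.seed(config$seed + 3L)
  runday_idx <- sample.int(config$n_rundays, n, replace = TRUE)
  scale <- 2^stats::rnorm(config$n_rundays, 0, config$runday_scale_sd)
  raw <- 2^x * scale[runday_idx]

  # --- metabolite ids and annotations ---
  n_unknown <- round(config$unknown_fraction * length(nonmod))
  unknown_idx <- if (n_unknown > 0) utils::tail(nonmod, n_unknown) else integer(0)
  ids <- sprintf("M%04d", seq_len(p))
  ids[unknown_idx] <- sprintf("X-%04d", unknown_idx)
  supers <- c("Amino acid", "Lipid", "Carbohydrate", "Nucleotide", "Energy",
              "Peptide", "Cofactors and vitamins", "Xenobiotics")
  super_pw <- supers[(seq_len(p) - 1L) %% length(supers) + 1L]
  sub_pw <- paste0("background_", (seq_len(p) - 1L) %/% 10L + 1L)
  for (k in seq_along(modules)) {
    super_pw[modules[[k]]] <- supers[(k - 1L) %% length(supers) + 1L]
    sub_pw[modules[[k]]] <- sprintf("module_%02d", k)
  }
  super_pw[unknown_idx] <- NA_character_
  sub_pw[unknown_idx] <- NA_character_
  annotations <- data.frame(metabolite_id = ids, super_pathway = super_pw,
                            sub_pathway = sub_pw, stringsAsFactors = FALSE)

  colnames(raw) <- ids
  rownames(raw) <- sprintf("S%04d", seq_len(n))
  if (!is.null(genotypes)) rownames(genotypes) <- rownames(raw)

  # --- missingness ---
  set.seed(config$seed + 4L)
  rates <- stats::runif(p, config$missing_rate_range[1],
                        config$missing_rate_range[2])
  if (config$missing_mechanism == "mcar") {
    mask <- matrix(stats::runif(n * p), n, p) <= rep(rates, each = n)
  } else {
    mask <- vapply(seq_len(p), function(j)
      raw[, j] <= stats::quantile(raw[, j], rates[j]) & rates[j] > 0,
      logical(n))
  }
  raw[mask] <- NA_real_

  covariates <- data.frame(gender = gender, age = age, bmi = bmi,
                           row.names = rownames(raw))
  truth <- list(
    modules = stats::setNames(lapply(modules, function(ix) ids[ix]),
                              sprintf("module_%02d", seq_along(modules))),
    gender_effects = eff,
    missing_rates = stats::setNames(rates, ids),
    dimorphic_snps = if (!is.null(dimorphic))
      data.frame(dimorphic[1],
                 metabolite_id = ids[dimorphic$metabolite_index],
                 dimorphic[3:4], stringsAsFactors = FALSE) else NULL,
    seed = config$seed)

  structure(list(metabolites = metabolite_matrix(raw,
                                                 paste0("D", runday_idx)),
                 covariates = covariates,
                 annotations = annotations,
                 genotypes = genotypes,
                 truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d metabolites (%d planted modules), %s SNPs\n",
              nrow(x$metabolites$values), ncol(x$metabolites$values),
              length(x$truth$modules),
              if (is.null(x$genotypes)) "no" else ncol(x$genotypes)))
  invisible(x)
}

#' Write / read a synthetic cohort as a plain-text file set
#'
#' Emits `metabolites.tsv`, `covariates.tsv`, `annotations.tsv`,
#' `dosages.tsv` (only when genotypes are present) and `truth.json` into a
#' directory. The files round-trip losslessly through the package readers.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param directory Output directory, created if needed.
#' @return `write_cohort()` the directory path (invisibly); `read_cohort()`
#'   a list with the same components re-read from disk.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_metabolite_matrix(cohort$metabolites,
                          file.path(directory, "metabolites.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(cohort$covariates), cohort$covariates),
    file.path(directory, "covariates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotations,
                     file.path(directory, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(cohort$genotypes)) {
    utils::write.table(
      data.frame(sample_id = rownames(cohort$genotypes), cohort$genotypes,
                 check.names = FALSE),
      file.path(directory, "dosages.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  dosage_path <- file.path(directory, "dosages.tsv")
  list(
    metabolites = read_metabolite_matrix(file.path(directory,
                                                   "metabolites.tsv")),
    covariates = read_covariate_table(file.path(directory, "covariates.tsv")),
    annotations = read_annotation_table(file.path(directory,
                                                  "annotations.tsv")),
    genotypes = if (file.exists(dosage_path)) read_dosage_matrix(dosage_path),
    truth = jsonlite::read_json(file.path(directory, "truth.json"),
                                simplifyVector = TRUE))
}
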