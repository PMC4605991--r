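#' Residualize metabolites on age within one gender stratum
#'
#' For the sex-stratified GWAS, each log2 metabolite is replaced, within the
#' requested stratum, by its OLS residuals from a regression on age (with
#' intercept), without any further adjustment. Missing entries stay
#' missing. When age is constant within the stratum, intercept-only
#' residuals (centering) are returned with a warning.
#'
#' @param m Log2-scale [metabolite_matrix()].
#' @param cov Covariate data frame (`gender` female = 1, `age`).
#' @param stratum `"female"` or `"male"`.
#' @return A `MetaboliteMatrix` restricted to the stratum's samples,
#'   containing residuals (mean exactly 0 per metabolite over its observed
#'   entries).
#' @export
residualize_by_age <- function(m, cov, stratum = c("female", "male")) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  stratum <- match.arg(stratum)
  cov <- .check_covariates(m, cov)
  sel <- cov$gender == if (stratum == "female") 1 else 0
  if (!any(sel)) stop("empty stratum: ", stratum)
  vals <- m$values[sel, , drop = FALSE]
  age <- cov$age[sel]
  const_age <- stats::sd(age) == 0
  if (const_age)
    warning("age constant within stratum; returning centered values")
  for (j in seq_len(ncol(vals))) {
    obs <- !is.na(vals[, j])
    if (sum(obs) < 2) next
    y <- vals[obs, j]
    vals[obs, j] <- if (const_age) y - mean(y) else
      stats::lm.fit(cbind(1, age[obs]), y)$residuals
  }
  metabolite_matrix(vals, m$runday[sel])
}

# vectorized per-SNP simple OLS with intercept: y on each column of D.
# Returns beta, se, n, p per SNP; monomorphic SNPs get NA with a reason.
.snp_scan <- function(y, D, min_n = 250) {
  obs <- !is.na(y)
  yv <- y[obs]
  Dv <- D[obs, , drop = FALSE]
  n <- length(yv)
  out <- data.frame(beta = rep(NA_real_, ncol(D)), se = NA_real_,
                    n = n, p = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  if (n < min_n) {
    out$reason <- sprintf("fewer than %d complete pairs", min_n)
    return(out)
  }
  yc <- yv - mean(yv)
  Dc <- sweep(Dv, 2, colMeans(Dv))
  sdd <- colSums(Dc^2)
  mono <- sdd < .Machine$double.eps * n
  sxy <- colSums(Dc * yc)
  beta <- sxy / sdd
  rss <- pmax(sum(yc^2) - beta * sxy, 0)
  df <- n - 2
  se <- sqrt(rss / df / sdd)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  out$beta <- beta; out$se <- se; out$p <- p
  out$beta[mono] <- out$se[mono] <- out$p[mono] <- NA_real_
  out$reason[mono] <- "zero dosage variance"
  out
}

#' Additive SNP effect on one metabolite within a stratum
#'
#' OLS of the age-residualized metabolite on the SNP dosage with intercept.
#' Pairs with a missing metabolite value are dropped; the fit is skipped
#' (with a reason) when fewer than `min_n` complete pairs remain or the
#' dosage has zero variance.
#'
#' @param residuals Numeric vector of age-residualized metabolite values
#'   (may contain `NA`).
#' @param dosage Numeric vector of allele dosages in \[0, 2\].
#' @param min_n Minimum complete pairs (default 250, mirroring the
#'   valid-measurement filter of the stratified analysis).
#' @param snp_id,metabolite_id,stratum Optional labels carried through.
#' @return One-row data frame: `metabolite_id`, `snp_id`, `stratum`,
#'   `beta`, `se`, `n`, `p`, `reason` (`NA` when fitted).
#' @export
fit_snp <- function(residuals, dosage, min_n = 250, snp_id = NA,
                    metabolite_id = NA, stratum = NA) {
  stopifnot(length(residuals) == length(dosage))
  keep <- !is.na(dosage)
  res <- .snp_scan(residuals[keep], matrix(dosage[keep], ncol = 1), min_n)
  data.frame(metabolite_id = metabolite_id, snp_id = snp_id,
             stratum = stratum, res, stringsAsFactors = FALSE)
}

#' Sex-heterogeneity (dimorphism) test on stratified effect estimates
#'
#' Compares the per-stratum additive SNP effects with
#' `z = (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)`, which is approximately
#' standard normal under the null of equal effects; the p-value is
#' two-sided normal. The denominator adds the two squared standard errors
#' (the variance of a difference of independent estimates).
#'
#' @param beta_f,se_f,beta_m,se_m Numeric vectors of per-stratum estimates
#'   and standard errors (recycled as usual).
#' @return Data frame `z`, `p`.
#' @examples
#' dimorphism_test(0.3, 0.05, 0, 0.05)  # z = 4.243
#' @export
dimorphism_test <- function(beta_f, se_f, beta_m, se_m) {
  v <- se_f^2 + se_m^2
  if (any(!is.na(v) & v <= 0))
    stop("non-positive variance sum in dimorphism test")
  z <- (beta_f - beta_m) / sqrt(v)
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Sex-stratified metabolite GWAS scan
#'
#' Full scan: metabolites are filtered to those with at least `min_valid`
#' valid measurements in each stratum, residualized on age per stratum,
#' regressed on every SNP's dosage per stratum, and the stratum betas are
#' compared with [dimorphism_test()]. Genome-wide significance uses the
#' conventional threshold `alpha_gw` further Bonferroni-corrected for the
#' number of metabolites tested (e.g. 5e-8 / 465 = 1.08e-10).
#'
#' @param m Log2-scale [metabolite_matrix()].
#' @param cov Covariate data frame.
#' @param dosages Numeric matrix samples x SNPs (dosages in \[0, 2\]), row
#'   names matching the matrix's sample ids.
#' @param min_valid Minimum valid measurements per stratum (default 250).
#' @param alpha_gw Genome-wide alpha before the metabolite correction
#'   (default 5e-8).
#' @return Data frame with one row per metabolite x SNP:
#'   `metabolite_id`, `snp_id`, `beta_f`, `se_f`, `n_f`, `p_f`, `beta_m`,
#'   `se_m`, `n_m`, `p_m`, `z`, `p`, `significant`. Attributes: `threshold`,
#'   `n_metabolites_tested`, `skipped` (metabolites failing the filter and
#'   pairs skipped inside the scan, with reasons).
#' @export
genomewide_scan <- function(m, cov, dosages, min_valid = 250,
                            alpha_gw = 5e-8) {
  stopifnot(inherits(m, "MetaboliteMatrix"), is.matrix(dosages))
  cov <- .check_covariates(m, cov)
  ids <- sample_ids(m)
  if (!all(ids %in% rownames(dosages)))
    stop("dosage matrix does not cover all samples")
  dosages <- dosages[ids, , drop = FALSE]

  strata <- list(female = cov$gender == 1, male = cov$gender == 0)
  nvalid <- vapply(strata, function(sel)
    colSums(!is.na(m$values[sel, , drop = FALSE])), numeric(ncol(m$values)))
  keep <- rowSums(nvalid >= min_valid) == 2
  skipped_met <- data.frame(
    metabolite_id = metabolite_ids(m)[!keep],
    reason = rep(sprintf("fewer than %d valid measurements in a stratum",
                         min_valid), sum(!keep)),
    stringsAsFactors = FALSE)
  mets <- metabolite_ids(m)[keep]
  if (!length(mets)) stop("no metabolite passes the valid-measurement filter")

  res_f <- residualize_by_age(m, cov, "female")
  res_m <- residualize_by_age(m, cov, "male")
  D_f <- dosages[strata$female, , drop = FALSE]
  D_m <- dosages[strata$male, , drop = FALSE]

  rows <- lapply(mets, function(id) {
    f <- .snp_scan(res_f$values[, id], D_f, min_n = min_valid)
    g <- .snp_scan(res_m$values[, id], D_m, min_n = min_valid)
    ok <- is.na(f$reason) & is.na(g$reason)
    dt <- dimorphism_test(f$beta, f$se, g$beta, g$se)
    data.frame(metabolite_id = id, snp_id = colnames(dosages),
               beta_f = f$beta, se_f = f$se, n_f = f$n, p_f = f$p,
               beta_m = g$beta, se_m = g$se, n_m = g$n, p_m = g$p,
               z = dt$z, p = dt$p,
               reason = ifelse(ok, NA_character_,
                               ifelse(is.na(f$reason), g$reason, f$reason)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- alpha_gw / length(mets)
  out$significant <- !is.na(out$p) & out$p < thr
  skipped_pairs <- out[!is.na(out$reason), c("metabolite_id", "snp_id",
                                             "reason")]
  out <- out[is.na(out$reason), setdiff(colnames(out), "reason")]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_metabolites_tested") <- length(mets)
  attr(out, "skipped") <- list(metabolites = skipped_met,
                               pairs = skipped_pairs)
  out
}
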