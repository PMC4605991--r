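# shared OLS core: response regressed on gender (+ covariates), with the
# gender coefficient, its partial r-squared and sample count extracted
.gender_lm <- function(y, cov, covariates = c("age", "bmi"),
                       min_cases = 10) {
  stopifnot(length(y) == nrow(cov))
  dat <- data.frame(y = as.numeric(y), gender = cov$gender)
  for (v in covariates) dat[[v]] <- cov[[v]]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < min_cases)
    stop(sprintf("only %d complete cases (need >= %d)", n, min_cases))
  if (length(unique(dat$gender)) < 2)
    stop("degenerate design: a single gender present among complete cases")
  if (stats::sd(dat$y) == 0)
    stop("zero variance in the response")
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design matrix")
  cf <- summary(fit)$coefficients
  tval <- cf["gender", 3]
  df <- fit$df.residual
  list(beta = unname(cf["gender", 1]), se = unname(cf["gender", 2]),
       p = unname(cf["gender", 4]), n = n,
       r2_partial = unname(tval^2 / (tval^2 + df)),
       r2_marginal = unname(stats::cor(dat$gender, dat$y)^2),
       df = df)
}

#' Covariate-adjusted gender association for one metabolite
#'
#' Ordinary least squares of the log2 concentration on gender with age and
#' BMI as covariates (equivalent to a covariate-adjusted two-group
#' comparison, since gender is dichotomous). Samples with a missing value
#' for the metabolite are dropped, so the effective N varies per metabolite.
#' Gender is coded female = 1, male = 0, so a negative beta means higher
#' concentrations in males.
#'
#' @param m Log2-scale [metabolite_matrix()].
#' @param cov Covariate data frame with `gender`, `age`, `bmi`, row names =
#'   sample ids.
#' @param metabolite_id Column to test.
#' @param covariates Adjustment covariates (default `c("age","bmi")`; use
#'   `character(0)` for an unadjusted two-group fit).
#' @param r2 Which explained-variance measure to report for the gender term:
#'   `"partial"` (squared partial correlation of gender with the outcome
#'   given the covariates; default) or `"marginal"` (unadjusted squared
#'   correlation).
#' @return One-row data frame: `metabolite_id`, `beta`, `se`, `r2`, `n`,
#'   `p`, `direction` (`"higher-in-males"` iff `beta < 0`).
#' @export
fit_gender_association <- function(m, cov, metabolite_id,
                                   covariates = c("age", "bmi"),
                                   r2 = c("partial", "marginal")) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  r2 <- match.arg(r2)
  if (!metabolite_id %in% metabolite_ids(m))
    stop("metabolite not present: ", metabolite_id)
  cov <- .check_covariates(m, cov)
  fit <- .gender_lm(m$values[, metabolite_id], cov, covariates)
  data.frame(metabolite_id = metabolite_id, beta = fit$beta, se = fit$se,
             r2 = if (r2 == "partial") fit$r2_partial else fit$r2_marginal,
             n = fit$n, p = fit$p,
             direction = if (fit$beta < 0) "higher-in-males" else
               "higher-in-females",
             stringsAsFactors = FALSE)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests, >= 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 507)   # 9.86e-05
#' bonferroni_threshold(5e-8, 465)   # 1.08e-10
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Gender association scan across all metabolites
#'
#' Runs [fit_gender_association()] for every metabolite and flags
#' significance at the Bonferroni level `alpha / (number of metabolites
#' tested)`. Metabolites whose fit fails (too few cases, zero variance,
#' degenerate design) are skipped and reported.
#'
#' @inheritParams fit_gender_association
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @return Data frame of association results sorted as the input columns,
#'   with a `significant` flag; attributes `threshold` (the Bonferroni
#'   level), `n_tests` and `skipped` (data frame of id + reason).
#' @export
run_association_scan <- function(m, cov, alpha = 0.05,
                                 covariates = c("age", "bmi"),
                                 r2 = c("partial", "marginal")) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  r2 <- match.arg(r2)
  cov <- .check_covariates(m, cov)
  ids <- metabolite_ids(m)
  rows <- vector("list", length(ids))
  skipped <- list()
  for (j in seq_along(ids)) {
    res <- tryCatch(
      fit_gender_association(m, cov, ids[j], covariates, r2),
      error = function(e)
        data.frame(metabolite_id = ids[j], reason = conditionMessage(e),
                   stringsAsFactors = FALSE))
    if ("reason" %in% colnames(res)) skipped[[length(skipped) + 1]] <- res
    else rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(metabolite_id = character(0), beta = numeric(0),
                      se = numeric(0), r2 = numeric(0), n = integer(0),
                      p = numeric(0), direction = character(0),
                      significant = logical(0))
  n_tests <- nrow(out)
  thr <- if (n_tests >= 1) bonferroni_threshold(alpha, n_tests) else NA_real_
  out$significant <- out$p < thr
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  attr(out, "n_tests") <- n_tests
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(metabolite_id = character(0), reason = character(0))
  out
}

#' Replication comparison between a discovery and a replication cohort
#'
#' Joins discovery-significant metabolites onto the replication scan by
#' metabolite id. A hit is `replicated` when the replication beta has the
#' same sign and the replication p-value falls below a Bonferroni level of
#' `alpha / (number of discovery-significant metabolites that were measured
#' in the replication cohort)`. Metabolites absent from the replication scan
#' get status `not-measured`.
#'
#' @param discovery,replication Results of [run_association_scan()] on the
#'   two cohorts (the discovery scan must carry its `significant` flags).
#' @param alpha Family-wise level for the replication threshold.
#' @return Data frame with one row per discovery-significant metabolite:
#'   discovery `beta`/`p`, `repl_beta`/`repl_p`, `same_direction`,
#'   `replicated`, `status` in `{replicated, not-replicated, not-measured}`;
#'   attribute `repl_threshold`.
#' @export
compare_cohorts <- function(discovery, replication, alpha = 0.05) {
  for (tab in list(discovery, replication))
    if (anyDuplicated(tab$metabolite_id))
      stop("duplicate metabolite ids in association results")
  disc <- discovery[discovery$significant %in% TRUE, , drop = FALSE]
  idx <- match(disc$metabolite_id, replication$metabolite_id)
  measured <- !is.na(idx)
  n_tested <- sum(measured)
  thr <- if (n_tested >= 1) bonferroni_threshold(alpha, n_tested) else
    NA_real_
  repl_beta <- repl_p <- rep(NA_real_, nrow(disc))
  repl_beta[measured] <- replication$beta[idx[measured]]
  repl_p[measured] <- replication$p[idx[measured]]
  same_dir <- sign(repl_beta) == sign(disc$beta)
  replicated <- measured & same_dir & repl_p < thr
  out <- data.frame(metabolite_id = disc$metabolite_id, beta = disc$beta,
                    p = disc$p, repl_beta = repl_beta, repl_p = repl_p,
                    same_direction = same_dir,
                    replicated = replicated,
                    status = ifelse(!measured, "not-measured",
                                    ifelse(replicated, "replicated",
                                           "not-replicated")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "repl_threshold") <- thr
  attr(out, "n_tested_in_replication") <- n_tested
  out
}

#' Export association results as a Table-1-style TSV
#'
#' @param scan Result of [run_association_scan()].
#' @param path Output file.
#' @param replication Optional result of [compare_cohorts()] to merge in.
#' @return The path, invisibly.
#' @export
write_association_table <- function(scan, path, replication = NULL) {
  out <- scan
  if (!is.null(replication)) {
    idx <- match(out$metabolite_id, replication$metabolite_id)
    out$repl_p <- replication$repl_p[idx]
    out$repl_direction <- ifelse(is.na(idx), NA,
                                 ifelse(replication$same_direction[idx],
                                        "Same", "Different"))
    out$replicated <- replication$replicated[idx]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
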