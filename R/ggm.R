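#' Missingness filter and normal-draw imputation
#'
#' Prepares a log2-scale matrix for partial-correlation estimation, which
#' needs complete data: metabolites with a missing fraction above
#' `max_missing_frac` (default 0.9, i.e. more than 90\% missing) are
#' removed, and every remaining missing entry is replaced by an independent
#' draw from a normal distribution with the mean and SD of that metabolite's
#' observed values. Adding such unstructured noise can only dilute
#' correlations, biasing the downstream network toward false-negative (not
#' false-positive) edges. Draws are unconstrained -- they may fall outside
#' the observed range. Deterministic given `seed`.
#'
#' @param m Log2-scale [metabolite_matrix()].
#' @param max_missing_frac Removal threshold on the missing fraction
#'   (strictly greater than; default 0.9).
#' @param seed Integer seed for the imputation draws.
#' @return A complete `MetaboliteMatrix`; attribute `removed` lists the
#'   metabolites dropped by the missingness filter (or for having fewer
#'   than two observed values, with a warning).
#' @export
impute_missing <- function(m, max_missing_frac = 0.9, seed = 1) {
  stopifnot(inherits(m, "MetaboliteMatrix"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  vals <- m$values
  frac <- colMeans(is.na(vals))
  nobs <- colSums(!is.na(vals))
  drop_missing <- frac > max_missing_frac
  drop_few <- !drop_missing & nobs < 2
  if (any(drop_few))
    warning("removing metabolite(s) with fewer than 2 observed values: ",
            paste(colnames(vals)[drop_few], collapse = ", "))
  removed <- colnames(vals)[drop_missing | drop_few]
  vals <- vals[, !(drop_missing | drop_few), drop = FALSE]
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (any(miss)) {
      obs <- vals[!miss, j]
      vals[miss, j] <- stats::rnorm(sum(miss), mean(obs), stats::sd(obs))
    }
  }
  out <- metabolite_matrix(vals, m$runday)
  attr(out, "removed") <- removed
  out
}

#' Gaussian graphical model: full-order partial correlations
#'
#' Estimates the partial correlation between every pair of metabolites
#' conditioned on all other metabolites plus the covariates (gender, age,
#' BMI by default). Covariates are conditioned on by appending them as
#' columns of the joint data matrix, which is equivalent to residualizing
#' on them. Note that gender is deliberately part of the conditioning set
#' even though it is also the phenotype of interest downstream: the network
#' is meant to capture metabolite-metabolite relations net of all measured
#' covariates, and cluster enrichment re-introduces gender afterwards.
#'
#' The estimator inverts the sample covariance of the joint matrix (valid
#' when samples comfortably exceed variables); the partial correlation is
#' `-omega_ij / sqrt(omega_ii * omega_jj)` from the precision matrix
#' `omega`. For undersampled problems a ridge-regularized inverse is
#' available via `ridge > 0`.
#'
#' @param m Complete log2-scale [metabolite_matrix()] (run
#'   [impute_missing()] first if needed).
#' @param cov Covariate data frame, or `NULL` to condition on metabolites
#'   only.
#' @param covariates Which covariate columns to condition on.
#' @param ridge Ridge penalty added to the covariance diagonal, as a
#'   fraction of the mean diagonal (default 0 = unregularized).
#' @return A `pcor_network`: list with `pcor` (symmetric metabolite x
#'   metabolite matrix, unit diagonal, entries in \[-1, 1\]),
#'   `metabolite_ids`, `n` (samples used) and `conditioned_on`.
#' @export
partial_correlations <- function(m, cov = NULL,
                                 covariates = c("gender", "age", "bmi"),
                                 ridge = 0) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  if (anyNA(m$values))
    stop("matrix contains missing values; run impute_missing() first")
  x <- m$values
  if (!is.null(cov) && length(covariates)) {
    cov <- .check_covariates(m, cov)
    x <- cbind(x, as.matrix(cov[, covariates, drop = FALSE]))
  } else covariates <- character(0)
  n <- nrow(x); ptot <- ncol(x)
  if (n <= ptot && ridge == 0)
    stop(sprintf(paste0("undersampled: %d samples for %d variables; the ",
                        "sample covariance is singular -- use ridge > 0"),
                 n, ptot))
  s <- stats::cov(x)
  if (ridge > 0) s <- s + ridge * mean(diag(s)) * diag(ptot)
  omega <- tryCatch(solve(s), error = function(e)
    stop(sprintf("singular covariance (condition number %.3g): %s",
                 kappa(s), conditionMessage(e))))
  d <- sqrt(diag(omega))
  pc <- -omega / tcrossprod(d)
  pc <- (pc + t(pc)) / 2
  pc[pc > 1] <- 1; pc[pc < -1] <- -1
  diag(pc) <- 1
  keep <- seq_len(ncol(m$values))
  pc <- pc[keep, keep, drop = FALSE]
  structure(list(pcor = pc, metabolite_ids = metabolite_ids(m), n = n,
                 conditioned_on = covariates),
            class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf("pcor_network: %d metabolites, n = %d, conditioned on: %s\n",
              ncol(x$pcor), x$n,
              if (length(x$conditioned_on))
                paste(x$conditioned_on, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Export a partial-correlation network as an edge list
#'
#' Undirected edge list of metabolite pairs with `|pcor| >= threshold`
#' (ties at the threshold are included). The clustering itself is
#' cutoff-free; the threshold only serves visualization and export.
#'
#' @param net A `pcor_network`.
#' @param edge_threshold Minimum absolute partial correlation (>= 0).
#' @param path Optional TSV output file.
#' @return Data frame `node_a`, `node_b`, `weight` (signed pcor); no
#'   self-edges.
#' @export
export_network <- function(net, edge_threshold = 0, path = NULL) {
  stopifnot(inherits(net, "pcor_network"), edge_threshold >= 0)
  pc <- net$pcor
  ids <- colnames(pc)
  ut <- upper.tri(pc)
  sel <- ut & abs(pc) >= edge_threshold
  idx <- which(sel, arr.ind = TRUE)
  out <- data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                    weight = pc[sel], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight)), ]
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
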