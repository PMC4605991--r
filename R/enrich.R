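#' Z-score standardization per metabolite
#'
#' Transforms each metabolite to mean 0 and SD 1 over its non-missing
#' values; missing entries are preserved. Positive values then mean a
#' concentration above the population mean for that metabolite. Metabolites
#' with zero SD (or fewer than two observed values) are excluded with a
#' warning.
#'
#' @param m Log2-scale [metabolite_matrix()].
#' @param sd_type Denominator of the SD: `"sample"` (n-1, default) or
#'   `"population"` (n).
#' @return A `MetaboliteMatrix` of z-scores.
#' @export
zscore_matrix <- function(m, sd_type = c("sample", "population")) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  sd_type <- match.arg(sd_type)
  vals <- m$values
  nobs <- colSums(!is.na(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  if (sd_type == "population") sds <- sds * sqrt((nobs - 1) / nobs)
  bad <- nobs < 2 | is.na(sds) | sds == 0
  if (any(bad)) {
    warning("excluding zero-SD metabolite(s): ",
            paste(colnames(vals)[bad], collapse = ", "))
    vals <- vals[, !bad, drop = FALSE]
    mu <- mu[!bad]; sds <- sds[!bad]
  }
  z <- sweep(sweep(vals, 2, mu, "-"), 2, sds, "/")
  metabolite_matrix(z, m$runday)
}

#' Per-sample activity of a metabolite set
#'
#' The mean z-score over the set's member metabolites with non-missing
#' values, per sample -- a measure of average pathway (or cluster) activity.
#' A sample's activity is set to missing when fewer than `min_frac` of the
#' members are observed for it.
#'
#' @param z Z-scored matrix from [zscore_matrix()].
#' @param members Character vector of member metabolite ids.
#' @param min_frac Minimum fraction of members that must be observed
#'   (default 0.5).
#' @return Named numeric vector of per-sample activities.
#' @export
set_activity <- function(z, members, min_frac = 0.5) {
  stopifnot(inherits(z, "MetaboliteMatrix"))
  members <- unique(members)
  present <- intersect(members, metabolite_ids(z))
  if (!length(present)) stop("no set member present in the matrix")
  sub <- z$values[, present, drop = FALSE]
  nobs <- rowSums(!is.na(sub))
  act <- rowMeans(sub, na.rm = TRUE)
  act[nobs < min_frac * length(present) | nobs == 0] <- NA_real_
  act
}

#' Metabolite sets from pathway annotations
#'
#' Builds named member lists from the annotation table at the super- or
#' sub-pathway level. Metabolites without an annotation at that level
#' ("unknowns") are omitted -- they can still enter the network analysis,
#' but not pathway enrichment.
#'
#' @param annotations Data frame with `metabolite_id`, `super_pathway`,
#'   `sub_pathway`.
#' @param level `"super"` or `"sub"`.
#' @return Named list of character vectors of member ids.
#' @export
pathway_sets <- function(annotations, level = c("super", "sub")) {
  level <- match.arg(level)
  col <- if (level == "super") "super_pathway" else "sub_pathway"
  ann <- annotations[!is.na(annotations[[col]]) & annotations[[col]] != "", ]
  split(ann$metabolite_id, ann[[col]])
}

#' Directional set enrichment via aggregated z-scores
#'
#' For each set, the per-sample mean z-score ([set_activity()]) is regressed
#' on gender with age and BMI as covariates -- exactly the single-metabolite
#' model, applied to the aggregated activity. This detects coordinated
#' one-sided shifts of a set's members; sets whose members move in opposite
#' directions cancel out by construction. Significance is Bonferroni-
#' corrected over the number of sets tested. `signed_log10p` carries the
#' direction for plotting: negative = higher in females (beta > 0 under the
#' female = 1 coding), positive = higher in males.
#'
#' @param m Log2-scale [metabolite_matrix()].
#' @param cov Covariate data frame (`gender`, `age`, `bmi`).
#' @param sets Named list of member-id vectors, e.g. from [pathway_sets()]
#'   or [cluster_sets()].
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @param min_frac Passed to [set_activity()].
#' @param covariates,sd_type Passed to the regression / z-scoring.
#' @return Data frame with one row per set: `set_id`, `n_members`,
#'   `n_members_used`, `beta`, `se`, `n`, `p`, `signed_log10p`,
#'   `significant`, `status` (`"ok"` or the skip reason).
#' @export
enrich_sets <- function(m, cov, sets, alpha = 0.05, min_frac = 0.5,
                        covariates = c("age", "bmi"),
                        sd_type = c("sample", "population")) {
  stopifnot(inherits(m, "MetaboliteMatrix"), length(sets) >= 1)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sd_type <- match.arg(sd_type)
  cov <- .check_covariates(m, cov)
  z <- suppressWarnings(zscore_matrix(m, sd_type))
  rows <- lapply(names(sets), function(id) {
    members <- unique(sets[[id]])
    res <- tryCatch({
      act <- set_activity(z, members, min_frac)
      fit <- .gender_lm(act, cov, covariates)
      data.frame(set_id = id, n_members = length(members),
                 n_members_used = length(intersect(members,
                                                   metabolite_ids(z))),
                 beta = fit$beta, se = fit$se, n = fit$n, p = fit$p,
                 signed_log10p = sign(fit$beta) * log10(fit$p),
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(set_id = id, n_members = length(members),
                 n_members_used = 0L, beta = NA_real_, se = NA_real_,
                 n = NA_integer_, p = NA_real_, signed_log10p = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(out$status == "ok")
  thr <- if (n_tested >= 1) bonferroni_threshold(alpha, n_tested) else
    NA_real_
  out$significant <- out$p < thr
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "n_tests") <- n_tested
  out
}
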