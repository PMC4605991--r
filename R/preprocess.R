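#' Run-day median scaling
#'
#' Divides each metabolite, within each run day, by its median over the
#' non-missing measurements of that run day, so that every metabolite's
#' per-run-day median becomes one. This removes multiplicative instrument
#' drift between measurement batches. Missing entries stay missing; a
#' metabolite-runday block with no non-missing value is left unscaled with a
#' warning. The operation is idempotent.
#'
#' @param m A [metabolite_matrix()] of raw (positive) abundances.
#' @return A `MetaboliteMatrix` with per-run-day medians equal to one.
#' @export
median_scale_by_runday <- function(m) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  vals <- m$values
  unscaled <- character(0)
  for (d in unique(m$runday)) {
    rows <- m$runday == d
    med <- apply(vals[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    bad <- is.na(med) | med == 0
    if (any(bad))
      unscaled <- c(unscaled, paste0(colnames(vals)[bad], "@", d))
    med[bad] <- 1
    vals[rows, ] <- sweep(vals[rows, , drop = FALSE], 2, med, "/")
  }
  if (length(unscaled))
    warning("metabolite-runday block(s) without usable median left unscaled: ",
            paste(utils::head(unscaled, 5), collapse = ", "),
            if (length(unscaled) > 5) ", ...")
  metabolite_matrix(vals, m$runday)
}

#' Log2 transform
#'
#' Elementwise log2 of the (median-scaled) abundances; missing entries are
#' preserved. Non-positive values are an error, reported with the offending
#' metabolite and sample id.
#'
#' @param m A [metabolite_matrix()] with strictly positive non-missing values.
#' @return A `MetaboliteMatrix` on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "MetaboliteMatrix"))
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value for metabolite '%s', sample '%s'",
                 colnames(m$values)[bad[1, 2]], rownames(m$values)[bad[1, 1]]))
  metabolite_matrix(log2(m$values), m$runday)
}

# Kolmogorov-Smirnov distance of standardized x to the standard normal,
# with mean/SD estimated from the data (Lilliefors-style plug-in)
.ks_normal_stat <- function(x) {
  x <- x[!is.na(x)]
  unname(suppressWarnings(
    stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$statistic))
}

#' Compare normality of raw versus log2-scale concentrations
#'
#' For each metabolite, standardizes the non-missing values on both scales
#' and computes the Kolmogorov-Smirnov statistic against the standard
#' normal; the scale with the smaller statistic is flagged as closer to
#' normal. Metabolites with fewer than three non-missing values or zero SD
#' are skipped and noted.
#'
#' @param raw,logged Aligned `MetaboliteMatrix` objects (same samples and
#'   metabolites) on the raw and log2 scale.
#' @return A data frame (`NormalityReport`) with columns `metabolite_id`,
#'   `ks_raw`, `ks_log2`, `closer_to_normal` ("raw"/"log2") and `skipped`.
#'   The attribute `n_log2_closer` summarizes the per-metabolite vote.
#' @export
compare_normality <- function(raw, logged) {
  stopifnot(inherits(raw, "MetaboliteMatrix"),
            inherits(logged, "MetaboliteMatrix"),
            identical(dim(raw$values), dim(logged$values)),
            identical(colnames(raw$values), colnames(logged$values)))
  ids <- metabolite_ids(raw)
  res <- lapply(seq_along(ids), function(j) {
    x <- raw$values[, j]; y <- logged$values[, j]
    ok <- sum(!is.na(x)) >= 3 &&
      stats::sd(x, na.rm = TRUE) > 0 && stats::sd(y, na.rm = TRUE) > 0
    if (!ok)
      return(data.frame(metabolite_id = ids[j], ks_raw = NA_real_,
                        ks_log2 = NA_real_,
                        closer_to_normal = NA_character_, skipped = TRUE))
    kr <- .ks_normal_stat(x); kl <- .ks_normal_stat(y)
    data.frame(metabolite_id = ids[j], ks_raw = kr, ks_log2 = kl,
               closer_to_normal = if (kl < kr) "log2" else "raw",
               skipped = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_log2_closer") <- sum(out$closer_to_normal == "log2",
                                    na.rm = TRUE)
  out
}

#' Filter metabolites by valid measurements and variance
#'
#' Removes metabolites with fewer than `min_valid` non-missing measurements
#' or (optionally) zero variance; the order of the survivors is preserved.
#'
#' @param m A [metabolite_matrix()].
#' @param min_valid Minimum number of non-missing values (default 10).
#' @param require_variance Also drop zero-variance metabolites (default TRUE).
#' @return A list with elements `matrix` (the filtered `MetaboliteMatrix`)
#'   and `removed` (data frame of `metabolite_id` and `reason`).
#' @export
filter_metabolites <- function(m, min_valid = 10, require_variance = TRUE) {
  stopifnot(inherits(m, "MetaboliteMatrix"), min_valid >= 1)
  nvalid <- colSums(!is.na(m$values))
  sds <- apply(m$values, 2, stats::sd, na.rm = TRUE)
  few <- nvalid < min_valid
  flat <- require_variance & !few & (is.na(sds) | sds == 0)
  drop <- few | flat
  removed <- data.frame(
    metabolite_id = metabolite_ids(m)[drop],
    reason = ifelse(few[drop], sprintf("fewer than %d valid measurements",
                                       min_valid), "zero variance"),
    stringsAsFactors = FALSE)
  keep <- m$values[, !drop, drop = FALSE]
  list(matrix = metabolite_matrix(keep, m$runday), removed = removed)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper: [filter_metabolites()], then
#' [median_scale_by_runday()] (optional), then [log2_transform()] --
#' yielding the log2 matrix every downstream analysis consumes.
#'
#' @param m Raw `MetaboliteMatrix`.
#' @param min_valid,require_variance Passed to [filter_metabolites()].
#' @param runday_scaling Apply run-day median scaling (default TRUE).
#' @return A list with `matrix` (log2 `MetaboliteMatrix`) and `removed`.
#' @export
preprocess_cohort <- function(m, min_valid = 10, require_variance = TRUE,
                              runday_scaling = TRUE) {
  flt <- filter_metabolites(m, min_valid, require_variance)
  scaled <- if (runday_scaling) median_scale_by_runday(flt$matrix) else
    flt$matrix
  list(matrix = log2_transform(scaled), removed = flt$removed)
}
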