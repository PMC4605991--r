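#' Validate cohort input files
#'
#' Machine-readable pre-flight checks on the cohort file set: sample-id
#' alignment between metabolite, covariate and (optional) dosage files,
#' duplicated ids, missing covariates, non-numeric or out-of-range cells.
#' Reports issues instead of throwing.
#'
#' @param metabolites,covariates Paths to the abundance and covariate TSVs.
#' @param dosages,annotations Optional paths.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `check` and `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(metabolites, covariates, dosages = NULL,
                            annotations = NULL) {
  issues <- list()
  note <- function(severity, check, message)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, check = check, message = message,
      stringsAsFactors = FALSE)

  m <- tryCatch(read_metabolite_matrix(metabolites), error = function(e) {
    note("error", "metabolites_readable", conditionMessage(e)); NULL
  })
  cv <- tryCatch(read_covariate_table(covariates), error = function(e) {
    note("error", "covariates_readable", conditionMessage(e)); NULL
  })
  if (!is.null(m) && !is.null(cv)) {
    missing_cov <- setdiff(sample_ids(m), rownames(cv))
    if (length(missing_cov))
      note("error", "sample_alignment",
           sprintf("%d sample(s) lack covariates (e.g. %s)",
                   length(missing_cov), missing_cov[1]))
    if (anyDuplicated(rownames(cv)))
      note("error", "duplicate_sample_ids", "duplicated ids in covariates")
    need <- setdiff(c("gender", "age", "bmi"), colnames(cv))
    if (length(need))
      note("error", "covariate_columns",
           paste("missing column(s):", paste(need, collapse = ", ")))
    else {
      if (!all(cv$gender %in% c(0, 1, NA)))
        note("error", "gender_coding", "gender must be 0/1 (female = 1)")
      common <- intersect(sample_ids(m), rownames(cv))
      if (anyNA(cv[common, c("gender", "age", "bmi")]))
        note("warning", "covariate_missingness",
             "missing covariate values for analyzed samples")
    }
    if (all(colSums(!is.na(m$values)) == 0))
      note("error", "all_missing", "metabolite matrix entirely missing")
  }
  if (!is.null(dosages)) {
    d <- tryCatch(read_dosage_matrix(dosages), error = function(e) {
      note("error", "dosages_readable", conditionMessage(e)); NULL
    })
    if (!is.null(d) && !is.null(m)) {
      missing_d <- setdiff(sample_ids(m), rownames(d))
      if (length(missing_d))
        note("error", "dosage_alignment",
             sprintf("%d sample(s) lack dosages (e.g. %s)",
                     length(missing_d), missing_d[1]))
    }
  }
  if (!is.null(annotations)) {
    a <- tryCatch(read_annotation_table(annotations), error = function(e) {
      note("error", "annotations_readable", conditionMessage(e)); NULL
    })
    if (!is.null(a)) {
      if (anyDuplicated(a$metabolite_id))
        note("error", "duplicate_metabolite_ids",
             "duplicated metabolite ids in annotations")
      if (!is.null(m)) {
        unannotated <- setdiff(metabolite_ids(m), a$metabolite_id)
        if (length(unannotated))
          note("warning", "annotation_coverage",
               sprintf("%d metabolite(s) have no annotation row",
                       length(unannotated)))
      }
    }
  }
  if (!length(issues))
    return(data.frame(severity = character(0), check = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocess, single-metabolite association, pathway
#' enrichment (super- and sub-pathway), the Gaussian graphical model,
#' strongest-path clustering with quality and enrichment, and the optional
#' stratified GWAS and replication stages. All outputs (TSV tables, an edge
#' list and a JSON manifest recording versions, seeds and per-stage row
#' counts) are written into `output_dir`. Re-running with the same config
#' reproduces identical outputs.
#'
#' @param config Either a named list or a path to a YAML file with entries:
#'   `inputs` (paths `metabolites`, `covariates`, `annotations`, optional
#'   `dosages`), optional `replication` (paths `metabolites`,
#'   `covariates`), `output_dir`, and optional scalars `alpha` (0.05),
#'   `min_valid` (10), `runday_scaling` (TRUE), `max_missing_frac` (0.9),
#'   `k` (75), `n_restarts` (50), `edge_threshold` (0.1), `seed` (1),
#'   `gwas_min_valid` (250), `alpha_gw` (5e-8).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(alpha = 0.05, min_valid = 10, runday_scaling = TRUE,
                   max_missing_frac = 0.9, k = 75, n_restarts = 50,
                   edge_threshold = 0.1, seed = 1, gwas_min_valid = 250,
                   alpha_gw = 5e-8)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  ins <- config$inputs
  if (is.null(ins$metabolites) || is.null(ins$covariates) ||
      is.null(ins$annotations))
    stop("config error: inputs must name metabolites, covariates and annotations files")
  for (f in unlist(c(ins, config$replication)))
    if (!file.exists(f)) stop("config error: input file not found: ", f)
  if (is.null(config$output_dir)) stop("config error: output_dir missing")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  log_path <- file.path(config$output_dir, "pipeline.log")
  cat(sprintf("pipeline started, seed = %d\n", config$seed),
      file = log_path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    cat(sprintf("stage %-16s %.2fs\n", name, el), file = log_path,
        append = TRUE)
    message(sprintf("[metadimorph] stage %s done (%.2fs)", name, el))
    list(result = res, elapsed = el)
  }
  manifest <- list(
    package = as.character(utils::packageVersion("metadimorph")),
    r_version = R.version.string,
    seed = config$seed, k = config$k, alpha = config$alpha,
    stages = list())
  out <- list()

  s <- stage("preprocess", {
    raw <- read_metabolite_matrix(ins$metabolites)
    cov <- read_covariate_table(ins$covariates)
    ann <- read_annotation_table(ins$annotations)
    pp <- preprocess_cohort(raw, config$min_valid,
                            runday_scaling = config$runday_scaling)
    list(m = pp$matrix, cov = cov, ann = ann, removed = pp$removed)
  })
  pp <- s$result
  manifest$stages$preprocess <- list(n_samples = nrow(pp$m$values),
                                     n_metabolites = ncol(pp$m$values),
                                     n_removed = nrow(pp$removed))

  s <- stage("assoc", run_association_scan(pp$m, pp$cov, config$alpha))
  out$association <- s$result
  write_association_table(out$association,
                          file.path(config$output_dir, "association.tsv"))
  manifest$stages$assoc <- list(n_tests = attr(out$association, "n_tests"),
                                n_significant =
                                  sum(out$association$significant))

  s <- stage("enrich_pathways", {
    lapply(c(super = "super", sub = "sub"), function(lv)
      enrich_sets(pp$m, pp$cov, pathway_sets(pp$ann, lv),
                  alpha = config$alpha))
  })
  out$pathway_enrichment <- s$result
  for (lv in names(out$pathway_enrichment))
    utils::write.table(out$pathway_enrichment[[lv]],
                       file.path(config$output_dir,
                                 sprintf("enrichment_%s.tsv", lv)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$enrich_pathways <-
    list(n_sets = vapply(out$pathway_enrichment, nrow, integer(1)))

  s <- stage("ggm", {
    imp <- impute_missing(pp$m, config$max_missing_frac, seed = config$seed)
    net <- partial_correlations(imp, pp$cov)
    list(imp = imp, net = net)
  })
  net <- s$result$net
  imp <- s$result$imp
  out$network <- net
  export_network(net, config$edge_threshold,
                 file.path(config$output_dir, "network_edges.tsv"))
  manifest$stages$ggm <- list(n_nodes = ncol(net$pcor),
                              n_imputed_out =
                                length(attr(imp, "removed")))

  s <- stage("netcluster", {
    spm <- strongest_path_matrix(net)
    cl <- cluster_kmeans(spm, min(config$k, length(spm$node_ids)),
                         seed = config$seed,
                         n_restarts = config$n_restarts)
    summ <- summarize_clusters(cl, net, imp, pp$cov,
                               alpha = config$alpha)
    list(spm = spm, clusters = cl, summary = summ)
  })
  out$clusters <- s$result$clusters
  out$cluster_summary <- s$result$summary
  utils::write.table(out$cluster_summary,
                     file.path(config$output_dir, "cluster_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assign_tab <- data.frame(node_id = names(out$clusters$assignment),
                           cluster_id = sprintf("cluster_%d",
                                                out$clusters$assignment),
                           stringsAsFactors = FALSE)
  utils::write.table(assign_tab,
                     file.path(config$output_dir, "cluster_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$netcluster <-
    list(k = out$clusters$k,
         n_significant = sum(out$cluster_summary$significant, na.rm = TRUE))

  if (!is.null(config$replication)) {
    s <- stage("replication", {
      raw_r <- read_metabolite_matrix(config$replication$metabolites)
      cov_r <- read_covariate_table(config$replication$covariates)
      mr <- preprocess_cohort(raw_r, config$min_valid,
                              runday_scaling = config$runday_scaling)$matrix
      scan_r <- run_association_scan(mr, cov_r, config$alpha)
      list(scan = scan_r,
           assoc = compare_cohorts(out$association, scan_r, config$alpha),
           clusters = replicate_clusters(out$clusters, mr, cov_r,
                                         alpha = config$alpha))
    })
    out$replication <- s$result[c("assoc", "clusters")]
    utils::write.table(out$replication$assoc,
                       file.path(config$output_dir, "replication.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$replication$clusters,
                       file.path(config$output_dir,
                                 "cluster_replication.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$replication <-
      list(n_replicated = sum(out$replication$assoc$replicated,
                              na.rm = TRUE))
  }

  if (!is.null(ins$dosages)) {
    s <- stage("gwas", {
      genomewide_scan(pp$m, pp$cov, read_dosage_matrix(ins$dosages),
                      min_valid = config$gwas_min_valid,
                      alpha_gw = config$alpha_gw)
    })
    out$gwas <- s$result
    utils::write.table(out$gwas,
                       file.path(config$output_dir, "gwas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$gwas <- list(n_pairs = nrow(out$gwas),
                                 n_significant = sum(out$gwas$significant))
  }

  manifest$row_counts <- lapply(
    Filter(is.data.frame, out), nrow)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
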