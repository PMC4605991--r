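#' Multiplicative strongest-path similarity matrix
#'
#' A cutoff-free node similarity for partial-correlation networks: the edge
#' weight between two metabolites is the absolute partial correlation, and
#' the similarity of a pair is the maximum, over all paths connecting them
#' (through zero or more other metabolites), of the product of edge weights
#' along the path. Because all weights lie in \[0, 1\], products along
#' longer paths can only shrink, so optimal paths are simple and the exact
#' optimum is obtained by Dijkstra shortest paths on `-log(weight)`:
#' `spm = exp(-dist)`. The self-similarity is 1 (the empty product), and
#' `spm(i, j) >= |pcor(i, j)|` always -- an indirect path may beat the
#' direct edge. Unreachable pairs get similarity 0.
#'
#' @param net A `pcor_network` from [partial_correlations()].
#' @return A `strongest_paths` object: list with `spm` (symmetric matrix in
#'   \[0, 1\], unit diagonal) and `node_ids`.
#' @examples
#' # triangle: direct edge 0.2 is beaten by the 0.5 * 0.5 two-step path
#' pc <- diag(3); pc[1,2] <- pc[2,1] <- 0.5; pc[2,3] <- pc[3,2] <- 0.5
#' pc[1,3] <- pc[3,1] <- 0.2
#' dimnames(pc) <- list(c("A","B","C"), c("A","B","C"))
#' net <- structure(list(pcor = pc, metabolite_ids = c("A","B","C"),
#'                       n = 10, conditioned_on = character(0)),
#'                  class = "pcor_network")
#' strongest_path_matrix(net)$spm["A", "C"]  # 0.25
#' @export
strongest_path_matrix <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  w <- abs(net$pcor)
  diag(w) <- 0
  w[w > 1] <- 1
  if (is.null(colnames(w)))
    colnames(w) <- rownames(w) <- net$metabolite_ids
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = -log(igraph::E(g)$weight),
                         algorithm = "dijkstra")
  spm <- exp(-d)
  spm[is.infinite(d)] <- 0
  diag(spm) <- 1
  spm <- spm[colnames(w), colnames(w)]
  structure(list(spm = spm, node_ids = colnames(w)),
            class = "strongest_paths")
}

#' @export
print.strongest_paths <- function(x, ...) {
  cat(sprintf("strongest_paths: %d nodes, mean off-diagonal similarity %.3f\n",
              length(x$node_ids),
              mean(x$spm[upper.tri(x$spm)])))
  invisible(x)
}

#' k-means clustering of the strongest-path matrix
#'
#' Uses the rows of the strongest-path similarity matrix as feature vectors
#' and runs standard k-means (Euclidean distance) with `n_restarts` random
#' initializations, keeping the solution with the lowest within-cluster sum
#' of squares. Deterministic given `seed`. Empty clusters are handled by
#' `stats::kmeans`'s re-assignment; `k = n` yields singletons.
#'
#' @param spm A `strongest_paths` object.
#' @param k Number of clusters, `2 <= k <= n_nodes` (the ad-hoc choice for
#'   a ~500-metabolite serum panel is 75).
#' @param seed Integer seed.
#' @param n_restarts Random restarts (default 50).
#' @return A `cluster_set`: list with `k`, `assignment` (named integer
#'   vector node -> cluster id), `clusters` (list of member-id vectors),
#'   `tot_withinss` and `seed`.
#' @export
cluster_kmeans <- function(spm, k, seed = 1, n_restarts = 50) {
  stopifnot(inherits(spm, "strongest_paths"))
  x <- spm$spm
  n <- nrow(x)
  if (k < 1 || k > n) stop(sprintf("k = %d outside 1..%d", k, n))
  if (k == n) {
    assignment <- stats::setNames(seq_len(n), spm$node_ids)
    tot <- 0
  } else {
    set.seed(as.integer(seed))
    km <- suppressWarnings(stats::kmeans(x, centers = k,
                                         nstart = n_restarts,
                                         iter.max = 200))
    assignment <- stats::setNames(km$cluster, spm$node_ids)
    tot <- km$tot.withinss
  }
  structure(list(k = k, assignment = assignment,
                 clusters = split(spm$node_ids, assignment),
                 tot_withinss = tot, seed = as.integer(seed)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d nodes in k = %d clusters (sizes %s)\n",
              length(x$assignment), x$k,
              paste(range(lengths(x$clusters)), collapse = "-")))
  invisible(x)
}

#' Member sets of a clustering
#'
#' @param clusters A `cluster_set`.
#' @return Named list of member-id vectors (names `cluster_<id>`), usable
#'   with [enrich_sets()].
#' @export
cluster_sets <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  stats::setNames(clusters$clusters,
                  sprintf("cluster_%s", names(clusters$clusters)))
}

#' Maximum-spanning-tree cluster quality
#'
#' Scores how strongly a cluster's metabolites hang together in the
#' network: on the complete subgraph over the members, weighted by absolute
#' partial correlations, the maximum-weight spanning tree is the strongest
#' possible connection visiting every member exactly once; the quality is
#' the mean of its edge weights (bounded in \[0, 1\]). Unlike the mean over
#' all pairs, this respects the inherent sparsity of partial-correlation
#' networks. Size-1 clusters get quality 0 by convention. A geometric mean
#' of the tree edges is available as an alternative aggregation.
#'
#' @param members Character vector of member node ids.
#' @param net A `pcor_network`.
#' @param mean_type `"arithmetic"` (default) or `"geometric"`.
#' @return Scalar quality in \[0, 1\].
#' @export
cluster_quality <- function(members, net,
                            mean_type = c("arithmetic", "geometric")) {
  stopifnot(inherits(net, "pcor_network"))
  mean_type <- match.arg(mean_type)
  members <- unique(members)
  if (length(members) < 2) return(0)
  idx <- match(members, colnames(net$pcor))
  if (anyNA(idx)) stop("member(s) absent from the network")
  w <- abs(net$pcor[idx, idx])
  m <- length(members)
  g <- igraph::make_full_graph(m)
  ends <- igraph::as_edgelist(g)
  wvec <- w[ends]
  tree <- igraph::mst(g, weights = 1 - wvec)  # min of (1-w) = max of w
  tends <- igraph::as_edgelist(tree)
  tw <- w[tends]
  if (mean_type == "arithmetic") mean(tw) else
    if (any(tw == 0)) 0 else exp(mean(log(tw)))
}

#' Mean silhouette over a grid of k
#'
#' Evaluates cluster cohesion vs separation for each candidate k, in the
#' same feature space (rows of the strongest-path matrix) and metric
#' (Euclidean) as [cluster_kmeans()]. Values lie in \[-1, 1\]; `k = n` (or
#' `k = 1`) is undefined and reported as `NA` by convention.
#'
#' @param spm A `strongest_paths` object.
#' @param k_grid Integer vector of candidate k values.
#' @param seed,n_restarts Passed to [cluster_kmeans()].
#' @return Data frame `k`, `mean_silhouette`.
#' @export
silhouette_evaluation <- function(spm, k_grid, seed = 1, n_restarts = 50) {
  stopifnot(inherits(spm, "strongest_paths"))
  d <- stats::dist(spm$spm)
  n <- length(spm$node_ids)
  ms <- vapply(k_grid, function(k) {
    if (k < 2 || k >= n) return(NA_real_)
    cs <- cluster_kmeans(spm, k, seed, n_restarts)
    sil <- cluster::silhouette(as.integer(cs$assignment), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  data.frame(k = k_grid, mean_silhouette = ms)
}

# best Jaccard overlap of each reference cluster with any candidate cluster
.best_jaccard <- function(ref_clusters, cand_clusters) {
  vapply(ref_clusters, function(a)
    max(vapply(cand_clusters, function(b) {
      i <- length(intersect(a, b))
      i / (length(a) + length(b) - i)
    }, numeric(1))), numeric(1))
}

#' Bootstrap stability of the network clustering
#'
#' Resamples the cohort's samples with replacement `B` times and reruns the
#' whole network pipeline on each replicate (imputation, partial
#' correlations, strongest paths, k-means). Each original cluster's
#' stability is the mean, over replicates, of its best Jaccard overlap with
#' any replicate cluster. Replicates with a singular covariance are skipped
#' and counted.
#'
#' @param m Log2-scale [metabolite_matrix()] (missing values allowed; the
#'   imputation step handles them per replicate).
#' @param cov Covariate data frame.
#' @param k Number of clusters.
#' @param B Bootstrap replicates (default 100).
#' @param seed Integer seed (replicate b uses `seed + b`).
#' @param n_restarts k-means restarts per replicate (default 10 -- smaller
#'   than the main analysis, since many replicates are averaged).
#' @param max_missing_frac Passed to [impute_missing()].
#' @param covariates Conditioning covariates for the network.
#' @return List with `stability` (data frame `cluster_id`, `size`,
#'   `stability`), `n_failed` and `B`; plus the reference `clusters`.
#' @export
bootstrap_stability <- function(m, cov, k, B = 100, seed = 1,
                                n_restarts = 10, max_missing_frac = 0.9,
                                covariates = c("gender", "age", "bmi")) {
  stopifnot(inherits(m, "MetaboliteMatrix"), B >= 1)
  cov <- .check_covariates(m, cov)
  pipeline <- function(mm, cc, sd) {
    imp <- impute_missing(mm, max_missing_frac, seed = sd)
    net <- partial_correlations(imp, cc, covariates)
    cluster_kmeans(strongest_path_matrix(net), k, seed = sd, n_restarts)
  }
  ref <- pipeline(m, cov, seed)
  n <- nrow(m$values)
  overlaps <- matrix(NA_real_, B, length(ref$clusters))
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(as.integer(seed) + b)
    idx <- sample.int(n, n, replace = TRUE)
    vb <- m$values[idx, , drop = FALSE]
    rownames(vb) <- make.unique(rownames(vb))
    mb <- metabolite_matrix(vb, m$runday[idx])
    cb <- cov[idx, , drop = FALSE]
    rownames(cb) <- rownames(vb)
    res <- tryCatch(pipeline(mb, cb, seed + b), error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    overlaps[b, ] <- .best_jaccard(ref$clusters, res$clusters)
  }
  stab <- data.frame(cluster_id = names(ref$clusters),
                     size = lengths(ref$clusters),
                     stability = colMeans(overlaps, na.rm = TRUE),
                     stringsAsFactors = FALSE)
  rownames(stab) <- NULL
  list(stability = stab, n_failed = n_failed, B = B, clusters = ref)
}

#' Preservation of high-quality clusters across choices of k
#'
#' Checks that the clusters worth interpreting do not depend on the ad-hoc
#' number of clusters: metabolite groups with quality at least
#' `quality_threshold` (and size >= 2) at the reference k are matched, by
#' best Jaccard overlap, against the clusterings obtained at every other k
#' in the grid.
#'
#' @param spm A `strongest_paths` object.
#' @param net The underlying `pcor_network` (for quality scores).
#' @param k_grid Integer vector of k values (>= 2 values).
#' @param reference_k Which grid value defines the reference clusters
#'   (default: first element).
#' @param quality_threshold Minimum quality for a cluster to be tracked
#'   (default 0.25).
#' @param seed,n_restarts Passed to [cluster_kmeans()].
#' @return Data frame `cluster_id`, `size`, `quality`, `k`, `best_jaccard`
#'   (reference k included with overlap 1).
#' @export
k_robustness <- function(spm, net, k_grid, reference_k = k_grid[1],
                         quality_threshold = 0.25, seed = 1,
                         n_restarts = 50) {
  stopifnot(inherits(spm, "strongest_paths"), length(k_grid) >= 2,
            reference_k %in% k_grid)
  ref <- cluster_kmeans(spm, reference_k, seed, n_restarts)
  qual <- vapply(ref$clusters, cluster_quality, numeric(1), net = net)
  keep <- qual >= quality_threshold & lengths(ref$clusters) >= 2
  tracked <- ref$clusters[keep]
  if (!length(tracked))
    return(data.frame(cluster_id = character(0), size = integer(0),
                      quality = numeric(0), k = integer(0),
                      best_jaccard = numeric(0)))
  rows <- lapply(k_grid, function(k) {
    bj <- if (k == reference_k) rep(1, length(tracked)) else
      .best_jaccard(tracked,
                    cluster_kmeans(spm, k, seed, n_restarts)$clusters)
    data.frame(cluster_id = names(tracked), size = lengths(tracked),
               quality = qual[keep], k = k, best_jaccard = bj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate discovery clusters in a replication cohort
#'
#' Replication keeps the discovery cluster definitions fixed and re-tests
#' their gender enrichment on the replication cohort (the clustering itself
#' is not repeated). Members not measured in the replication cohort are
#' dropped from the activity average; clusters with no replicated member
#' get status `not-measured`.
#'
#' @param clusters A `cluster_set` from the discovery cohort.
#' @param m_repl,cov_repl Preprocessed (log2) replication matrix and
#'   covariates.
#' @param ... Passed to [enrich_sets()].
#' @return The [enrich_sets()] data frame on the replication cohort, with
#'   `status` set to `"not-measured"` for clusters without members there.
#' @export
replicate_clusters <- function(clusters, m_repl, cov_repl, ...) {
  stopifnot(inherits(clusters, "cluster_set"))
  sets <- cluster_sets(clusters)
  out <- enrich_sets(m_repl, cov_repl, sets, ...)
  out$status[out$n_members_used == 0] <- "not-measured"
  out
}

#' Per-cluster summary with quality and gender enrichment
#'
#' @param clusters A `cluster_set`.
#' @param net The `pcor_network` the clustering was derived from.
#' @param m,cov Optional log2 matrix + covariates; when given, cluster
#'   gender enrichment ([enrich_sets()]) is merged in.
#' @param alpha Family-wise level for the enrichment flags.
#' @param mean_type Passed to [cluster_quality()].
#' @return Data frame with one row per cluster: `cluster_id`, `size`,
#'   `quality`, and (if enrichment was run) `beta`, `p`, `signed_log10p`,
#'   `significant`, `direction`.
#' @export
summarize_clusters <- function(clusters, net, m = NULL, cov = NULL,
                               alpha = 0.05,
                               mean_type = c("arithmetic", "geometric")) {
  stopifnot(inherits(clusters, "cluster_set"))
  mean_type <- match.arg(mean_type)
  out <- data.frame(
    cluster_id = sprintf("cluster_%s", names(clusters$clusters)),
    size = lengths(clusters$clusters),
    quality = vapply(clusters$clusters, cluster_quality, numeric(1),
                     net = net, mean_type = mean_type),
    stringsAsFactors = FALSE)
  if (!is.null(m)) {
    enr <- enrich_sets(m, cov, cluster_sets(clusters), alpha = alpha)
    idx <- match(out$cluster_id, enr$set_id)
    out$beta <- enr$beta[idx]
    out$p <- enr$p[idx]
    out$signed_log10p <- enr$signed_log10p[idx]
    out$significant <- enr$significant[idx]
    out$direction <- ifelse(out$beta < 0, "higher-in-males",
                            "higher-in-females")
  }
  rownames(out) <- NULL
  out
}
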