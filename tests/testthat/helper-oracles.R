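# Independent brute-force oracles used to check the analytical
# implementations. These deliberately share no code with the package: path
# similarities come from exhaustive simple-path enumeration, spanning-tree
# qualities from enumeration over all spanning trees, and partial
# correlations from residual regressions.

# all permutations of a vector, as a list
perm_list <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# all ordered selections (permutations of subsets) of 1..m, by length;
# cached since they only depend on m
.ordered_subsets_cache <- new.env(parent = emptyenv())
ordered_subsets <- function(m) {
  key <- as.character(m)
  if (!is.null(.ordered_subsets_cache[[key]]))
    return(.ordered_subsets_cache[[key]])
  res <- lapply(seq_len(m), function(k) {
    cs <- utils::combn(m, k)
    do.call(rbind, unlist(lapply(seq_len(ncol(cs)), function(c)
      lapply(perm_list(cs[, c]), rbind)), recursive = FALSE))
  })
  .ordered_subsets_cache[[key]] <- res
  res
}

# exhaustive multiplicative strongest-path matrix: for each pair, maximum
# over ALL simple paths of the product of edge weights
brute_spm <- function(w) {
  n <- nrow(w)
  spm <- diag(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    others <- setdiff(seq_len(n), c(i, j))
    best <- w[i, j]
    if (length(others)) {
      os <- ordered_subsets(length(others))
      for (k in seq_along(os)) {
        S <- matrix(others[os[[k]]], nrow = nrow(os[[k]]))
        path <- cbind(i, S, j)
        pr <- rep(1, nrow(path))
        for (c in seq_len(ncol(path) - 1))
          pr <- pr * w[cbind(path[, c], path[, c + 1])]
        best <- max(best, pr)
      }
    }
    spm[i, j] <- spm[j, i] <- best
  }
  spm
}

# which (m-1)-edge subsets of the complete graph on m nodes are spanning
# trees; cached per m. Returns list(edges = 2-col matrix, trees = list of
# edge-index vectors)
.tree_cache <- new.env(parent = emptyenv())
spanning_trees <- function(m) {
  key <- as.character(m)
  if (!is.null(.tree_cache[[key]])) return(.tree_cache[[key]])
  ed <- t(utils::combn(m, 2))
  subsets <- utils::combn(nrow(ed), m - 1)
  is_tree <- logical(ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    parent <- seq_len(m)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in subsets[, s]) {
      a <- find(ed[e, 1]); b <- find(ed[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    is_tree[s] <- ok
  }
  res <- list(edges = ed,
              trees = lapply(which(is_tree), function(s) subsets[, s]))
  .tree_cache[[key]] <- res
  res
}

# exhaustive maximum-spanning-tree quality: max over ALL spanning trees of
# the mean edge weight... the maximizer of the mean is the maximizer of the
# sum since every tree has m-1 edges
brute_mst_quality <- function(w) {
  m <- nrow(w)
  if (m < 2) return(0)
  st <- spanning_trees(m)
  wv <- w[st$edges]
  best <- -Inf
  for (tr in st$trees) best <- max(best, mean(wv[tr]))
  best
}

# partial correlations by the residual-regression definition: correlate the
# residuals of i and j after regressing each on every other column
pcor_by_residuals <- function(x) {
  p <- ncol(x)
  out <- diag(p)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    rest <- cbind(1, x[, -c(i, j), drop = FALSE])
    ri <- stats::lm.fit(rest, x[, i])$residuals
    rj <- stats::lm.fit(rest, x[, j])$residuals
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}

# wrap a plain symmetric matrix as a pcor_network for the cluster functions
as_pcor_network <- function(pc, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("N%02d", seq_len(nrow(pc)))
  dimnames(pc) <- list(ids, ids)
  structure(list(pcor = pc, metabolite_ids = ids, n = NA_integer_,
                 conditioned_on = character(0)), class = "pcor_network")
}

# random symmetric weight matrix in [0,1] with zero diagonal
random_weights <- function(n, zero_frac = 0.2) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) < zero_frac] <- 0
  w[ut] <- vals
  w + t(w)
}

# labels of planted modules on a network's nodes (NA = background)
module_labels <- function(truth, node_ids) {
  lab <- rep(NA_integer_, length(node_ids))
  names(lab) <- node_ids
  for (i in seq_along(truth$modules)) lab[truth$modules[[i]]] <- i
  lab
}
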