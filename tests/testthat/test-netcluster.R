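# two well-separated blocks with weak background noise, as a direct
# partial-correlation matrix
two_block_net <- function(sizes = c(5, 5), w_in = 0.4, w_bg = 0.02,
                          seed = 1) {
  n <- sum(sizes)
  set.seed(seed)
  pc <- matrix(w_bg * runif(n * n), n, n)
  pc <- (pc + t(pc)) / 2
  b1 <- seq_len(sizes[1]); b2 <- seq(sizes[1] + 1, n)
  pc[b1, b1] <- w_in; pc[b2, b2] <- w_in
  diag(pc) <- 1
  as_pcor_network(pc)
}

test_that("strongest paths beat direct edges exactly when a product path wins", {
  pc <- diag(3)
  pc[1, 2] <- pc[2, 1] <- 0.5
  pc[2, 3] <- pc[3, 2] <- 0.5
  pc[1, 3] <- pc[3, 1] <- 0.2
  spm <- strongest_path_matrix(as_pcor_network(pc))$spm
  expect_equal(spm[1, 3], 0.25)       # 0.5 * 0.5 beats 0.2
  expect_equal(spm[1, 2], 0.5)        # direct edge optimal
  expect_equal(unname(diag(spm)), rep(1, 3))

  pc2 <- diag(2); pc2[1, 2] <- pc2[2, 1] <- 0.7
  expect_equal(strongest_path_matrix(as_pcor_network(pc2))$spm[1, 2], 0.7)

  # negative pcor enters through its absolute value
  pc3 <- diag(2); pc3[1, 2] <- pc3[2, 1] <- -0.6
  expect_equal(strongest_path_matrix(as_pcor_network(pc3))$spm[1, 2], 0.6)

  # disconnected nodes have similarity 0
  pc4 <- diag(3); pc4[1, 2] <- pc4[2, 1] <- 0.5
  expect_equal(strongest_path_matrix(as_pcor_network(pc4))$spm[1, 3], 0)
})

test_that("strongest paths equal exhaustive simple-path enumeration", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    w <- random_weights(n, zero_frac = 0.25)
    spm <- strongest_path_matrix(as_pcor_network(w + diag(n)))$spm
    expect_lt(max(abs(spm - brute_spm(w))), 1e-12)
    # dominance over the direct edge
    expect_true(all(spm >= w - 1e-12))
  }
})

test_that("MST quality matches forced examples and exhaustive enumeration", {
  pc <- diag(2); pc[1, 2] <- pc[2, 1] <- 0.4
  net <- as_pcor_network(pc)
  expect_equal(cluster_quality(c("N01", "N02"), net), 0.4)
  expect_equal(cluster_quality("N01", net), 0)   # singleton convention

  pc3 <- diag(3)
  pc3[1, 2] <- pc3[2, 1] <- 0.5
  pc3[1, 3] <- pc3[3, 1] <- 0.3
  pc3[2, 3] <- pc3[3, 2] <- 0.1
  net3 <- as_pcor_network(pc3)
  expect_equal(cluster_quality(c("N01", "N02", "N03"), net3), 0.4)
  expect_equal(cluster_quality(c("N01", "N02", "N03"), net3,
                               mean_type = "geometric"),
               sqrt(0.5 * 0.3))

  set.seed(12)
  for (i in 1:25) {
    n <- sample(4:7, 1)
    w <- random_weights(n, zero_frac = 0.1)
    net <- as_pcor_network(w + diag(n))
    expect_equal(cluster_quality(net$metabolite_ids, net),
                 brute_mst_quality(w), tolerance = 1e-12)
  }
})

test_that("k-means on the strongest-path matrix recovers planted blocks", {
  net <- two_block_net()
  spm <- strongest_path_matrix(net)
  cl <- cluster_kmeans(spm, 2, seed = 1)
  truth <- rep(1:2, each = 5)
  expect_equal(mclust::adjustedRandIndex(cl$assignment, truth), 1)

  # determinism and singleton edge case
  cl2 <- cluster_kmeans(spm, 2, seed = 1)
  expect_identical(cl$assignment, cl2$assignment)
  single <- cluster_kmeans(spm, 10, seed = 1)
  expect_identical(lengths(single$clusters),
                   stats::setNames(rep(1L, 10), as.character(1:10)))
  expect_error(cluster_kmeans(spm, 11), "outside")

  # planted block quality beats random same-size node sets
  q_block <- cluster_quality(spm$node_ids[1:5], net)
  set.seed(3)
  q_rand <- vapply(1:100, function(i)
    cluster_quality(sample(spm$node_ids, 5), net), numeric(1))
  expect_gt(mean(q_block > q_rand), 0.9)
})

test_that("silhouette peaks at the planted number of blocks and stays in range", {
  spm <- strongest_path_matrix(two_block_net())
  sil <- silhouette_evaluation(spm, 2:6, seed = 2)
  expect_identical(sil$k[which.max(sil$mean_silhouette)], 2L)
  expect_true(all(sil$mean_silhouette >= -1 & sil$mean_silhouette <= 1,
                  na.rm = TRUE))
  # k = n undefined by convention
  sil_n <- silhouette_evaluation(spm, c(2, 10), seed = 2)
  expect_true(is.na(sil_n$mean_silhouette[sil_n$k == 10]))
})

test_that("bootstrap stability separates structured from unstructured data", {
  cfg <- sim_config(n_samples = 300, n_metabolites = 20, n_modules = 4,
                    module_size_range = c(5, 5),
                    gender_effect_sizes = NULL,
                    missing_rate_range = c(0, 0.05), seed = 19)
  co <- simulate_cohort(cfg)
  logm <- preprocess_cohort(co$metabolites)$matrix
  bs <- bootstrap_stability(logm, co$covariates, k = 4, B = 15, seed = 19,
                            n_restarts = 10)
  expect_identical(nrow(bs$stability), 4L)
  expect_gt(mean(bs$stability$stability), 0.8)

  noise <- metabolite_matrix(matrix(rnorm(300 * 20),
                                    300, 20,
                                    dimnames = dimnames(logm$values)))
  bs0 <- bootstrap_stability(noise, co$covariates, k = 4, B = 15, seed = 19,
                             n_restarts = 10)
  expect_lt(mean(bs0$stability$stability),
            mean(bs$stability$stability) - 0.2)

  # B = 1 with a fixed seed is reproducible
  b1 <- bootstrap_stability(logm, co$covariates, k = 4, B = 1, seed = 5)
  b2 <- bootstrap_stability(logm, co$covariates, k = 4, B = 1, seed = 5)
  expect_identical(b1$stability, b2$stability)
})

test_that("high-quality clusters persist across the choice of k", {
  # one strong 10-node block inside a 60-node background network
  n <- 60
  set.seed(21)
  pc <- matrix(0.02 * runif(n * n), n, n); pc <- (pc + t(pc)) / 2
  pc[1:10, 1:10] <- 0.35
  diag(pc) <- 1
  net <- as_pcor_network(pc)
  spm <- strongest_path_matrix(net)
  rob <- k_robustness(spm, net, k_grid = c(6, 12, 20), reference_k = 6,
                      quality_threshold = 0.25, seed = 1, n_restarts = 20)
  block_rows <- rob[rob$size == 10, ]
  expect_gte(nrow(block_rows), 3)           # tracked at every k
  expect_true(all(block_rows$best_jaccard >= 0.8))
  # same spm and k twice: overlap exactly 1
  rob2 <- k_robustness(spm, net, k_grid = c(6, 6), reference_k = 6,
                       seed = 1, n_restarts = 20)
  expect_true(all(rob2$best_jaccard == 1))
})

test_that("cluster replication keeps discovery definitions fixed", {
  mk <- function(seed) simulate_cohort(sim_config(
    n_samples = 400, n_metabolites = 30, n_modules = 2,
    module_size_range = c(5, 5), gender_effect_sizes = c("1" = -1),
    seed = seed))
  d <- mk(33)
  logm <- preprocess_cohort(d$metabolites)$matrix
  net <- partial_correlations(impute_missing(logm, seed = 33), d$covariates)
  cl <- cluster_kmeans(strongest_path_matrix(net), 6, seed = 33)

  # the same cohort passed twice reproduces the discovery enrichment
  own <- enrich_sets(logm, d$covariates, cluster_sets(cl))
  again <- replicate_clusters(cl, logm, d$covariates)
  expect_equal(own$p, again$p)

  # an independent cohort replicates the planted dimorphic cluster
  r <- mk(34)
  logr <- preprocess_cohort(r$metabolites)$matrix
  rep_enr <- replicate_clusters(cl, logr, r$covariates)
  dim_cluster <- names(which.max(table(
    cl$assignment[d$truth$modules$module_01])))
  row <- rep_enr[rep_enr$set_id == paste0("cluster_", dim_cluster), ]
  expect_true(row$significant)

  # clusters made of metabolites absent from replication are not-measured
  sub <- metabolite_matrix(
    logr$values[, setdiff(colnames(logr$values),
                          d$truth$modules$module_02), drop = FALSE],
    logr$runday)
  rep2 <- replicate_clusters(cl, sub, r$covariates)
  c2 <- paste0("cluster_",
               names(which.max(table(
                 cl$assignment[d$truth$modules$module_02]))))
  miss_row <- rep2[rep2$set_id == c2, ]
  if (miss_row$n_members_used == 0)
    expect_identical(miss_row$status, "not-measured")
})

test_that("cluster summaries combine size, quality and enrichment", {
  co <- simulate_cohort(sim_config(n_samples = 400, n_metabolites = 30,
                                   n_modules = 2,
                                   module_size_range = c(5, 5),
                                   gender_effect_sizes = c("1" = -1),
                                   seed = 44))
  logm <- preprocess_cohort(co$metabolites)$matrix
  imp <- impute_missing(logm, seed = 44)
  net <- partial_correlations(imp, co$covariates)
  cl <- cluster_kmeans(strongest_path_matrix(net), 6, seed = 44)
  summ <- summarize_clusters(cl, net, imp, co$covariates)
  expect_identical(nrow(summ), 6L)
  expect_true(all(summ$quality >= 0 & summ$quality <= 1))
  sig <- summ$cluster_id[summ$significant]
  dim_cluster <- paste0("cluster_", names(which.max(table(
    cl$assignment[co$truth$modules$module_01]))))
  expect_true(dim_cluster %in% sig)
  expect_identical(unique(summ$direction[summ$cluster_id == dim_cluster]),
                   "higher-in-males")
})
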