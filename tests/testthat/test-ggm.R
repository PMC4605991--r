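test_that("missingness filter and normal-draw imputation behave as specified", {
  set.seed(7)
  n <- 200
  vals <- cbind(dense = rnorm(n, 5, 2),
                gappy = ifelse(runif(n) < 0.3, NA, rnorm(n, -2, 1)),
                empty95 = ifelse(runif(n) < 0.95, NA, rnorm(n)))
  m <- metabolite_matrix(vals)
  imp <- impute_missing(m, max_missing_frac = 0.9, seed = 1)
  expect_false("empty95" %in% metabolite_ids(imp))
  expect_identical(attr(imp, "removed"), "empty95")
  expect_false(anyNA(imp$values))
  # observed entries untouched
  obs <- !is.na(vals[, "gappy"])
  expect_equal(imp$values[obs, "gappy"], vals[obs, "gappy"],
               ignore_attr = TRUE)
  # imputed values follow the observed mean within sampling error
  mu <- mean(vals[obs, "gappy"]); s <- sd(vals[obs, "gappy"])
  expect_lt(abs(mean(imp$values[, "gappy"]) - mu), 4 * s / sqrt(n))
  # determinism and identity
  imp2 <- impute_missing(m, seed = 1)
  expect_identical(imp$values, imp2$values)
  nomiss <- metabolite_matrix(vals[, "dense", drop = FALSE])
  expect_identical(impute_missing(nomiss, seed = 3)$values, nomiss$values)
  # metabolites with < 2 observed values are removed with a warning
  m2 <- metabolite_matrix(cbind(one = c(1, rep(NA, 9)), ok = rnorm(10)))
  expect_warning(out <- impute_missing(m2, max_missing_frac = 0.95),
                 "fewer than 2")
  expect_identical(metabolite_ids(out), "ok")
})

test_that("with two variables and no conditioning, pcor equals Pearson correlation", {
  set.seed(2)
  x <- matrix(rnorm(100), 50, 2)
  net <- partial_correlations(metabolite_matrix(x), cov = NULL)
  expect_equal(net$pcor[1, 2], cor(x[, 1], x[, 2]), tolerance = 1e-10)
})

test_that("a mediated chain has near-zero partial correlation between the ends", {
  set.seed(3)
  n <- 5000
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, 0, 0.6); z <- 0.8 * y + rnorm(n, 0, 0.6)
  net <- partial_correlations(metabolite_matrix(cbind(x = x, y = y, z = z)),
                              cov = NULL)
  expect_lt(abs(net$pcor["x", "z"]), 0.05)
  expect_gt(net$pcor["x", "y"], 0.3)
  # the marginal correlation of the ends is far from zero
  expect_gt(cor(x, z), 0.3)
})

test_that("precision-matrix pcor matches the residual-regression definition", {
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(60 * 6), 60, 6)
    net <- partial_correlations(metabolite_matrix(x), cov = NULL)
    oracle <- pcor_by_residuals(x)
    expect_lt(max(abs(net$pcor - oracle)), 1e-8)
  }
  # also with covariate conditioning: oracle sees covariates as columns
  co <- simulate_cohort(sim_config(n_samples = 80, n_metabolites = 5,
                                   n_modules = 1,
                                   module_size_range = c(4, 4),
                                   missing_rate_range = c(0, 0), seed = 6))
  logm <- preprocess_cohort(co$metabolites)$matrix
  net <- partial_correlations(logm, co$covariates)
  joint <- cbind(logm$values, as.matrix(co$covariates))
  oracle <- pcor_by_residuals(joint)[1:5, 1:5]
  expect_lt(max(abs(net$pcor - oracle)), 1e-8)
})

test_that("network output is symmetric, unit-diagonal, bounded and covariate-free", {
  co <- simulate_cohort(sim_config(n_samples = 400, n_metabolites = 50,
                                   n_modules = 3, seed = 10))
  logm <- preprocess_cohort(co$metabolites)$matrix
  net <- partial_correlations(impute_missing(logm, seed = 1), co$covariates)
  expect_lt(max(abs(net$pcor - t(net$pcor))), 1e-10)
  expect_identical(unname(diag(net$pcor)), rep(1, 50))
  expect_true(all(net$pcor >= -1 & net$pcor <= 1))
  expect_identical(colnames(net$pcor), metabolite_ids(logm))
  expect_identical(net$conditioned_on, c("gender", "age", "bmi"))
})

test_that("planted blocks dominate the estimated partial correlations", {
  cfg <- sim_config(n_samples = 2000, seed = 14)
  co <- simulate_cohort(cfg)
  logm <- preprocess_cohort(co$metabolites)$matrix
  net <- partial_correlations(impute_missing(logm, seed = 14),
                              co$covariates)
  lab <- module_labels(co$truth, colnames(net$pcor))
  inmod <- which(!is.na(lab))
  within <- between <- c()
  for (i in inmod) for (j in inmod) if (i < j) {
    v <- abs(net$pcor[i, j])
    if (lab[i] == lab[j]) within <- c(within, v) else between <- c(between, v)
  }
  expect_gt(mean(within) - mean(between), 0.1)
})

test_that("imputation noise shrinks partial correlations toward zero", {
  deltas <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 500, n_metabolites = 15,
                                     n_modules = 3,
                                     module_size_range = c(5, 5),
                                     missing_rate_range = c(0, 0),
                                     gender_effect_sizes = NULL, seed = s))
    logm <- preprocess_cohort(co$metabolites)$matrix
    full <- partial_correlations(logm, co$covariates)
    vals <- logm$values
    set.seed(s)
    vals[runif(length(vals)) < 0.3] <- NA
    holey <- impute_missing(metabolite_matrix(vals, logm$runday), seed = s)
    neth <- partial_correlations(holey, co$covariates)
    lab <- module_labels(co$truth, colnames(full$pcor))
    same <- outer(lab, lab, "==")
    same[is.na(same)] <- FALSE
    w <- same & upper.tri(full$pcor)
    mean(abs(neth$pcor[w])) - mean(abs(full$pcor[w]))
  }, numeric(1))
  expect_lt(mean(deltas), 0)
})

test_that("undersampled problems are refused unless ridge regularization is on", {
  set.seed(8)
  x <- matrix(rnorm(20 * 30), 20, 30)
  m <- metabolite_matrix(x)
  expect_error(partial_correlations(m, cov = NULL), "undersampled")
  net <- partial_correlations(m, cov = NULL, ridge = 0.5)
  expect_true(all(is.finite(net$pcor)))
  expect_lt(max(abs(net$pcor - t(net$pcor))), 1e-10)
})

test_that("edge export respects thresholds and the >= tie rule", {
  pc <- diag(4)
  pc[1, 2] <- pc[2, 1] <- 0.5
  pc[1, 3] <- pc[3, 1] <- -0.5
  pc[2, 3] <- pc[3, 2] <- 0.2
  net <- as_pcor_network(pc)
  expect_identical(nrow(export_network(net, 0)), 6L)     # C(4,2)
  expect_identical(nrow(export_network(net, 1.01)), 0L)
  # both edges tied at |0.5| are kept with >= semantics
  tied <- export_network(net, 0.5)
  expect_identical(nrow(tied), 2L)
  expect_true(all(abs(tied$weight) == 0.5))
  # signed weights survive, no self-edges
  expect_true(any(tied$weight < 0))
  expect_true(all(tied$node_a != tied$node_b))
})
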