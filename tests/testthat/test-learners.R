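test_that("constant expression yields all-zero scores for every method", {
  set.seed(1)
  X <- matrix(rbinom(200, 1, 0.5), 20, 10)
  y <- rep(3.7, 20)
  lp <- tiny_learner(n_trees = 50)
  for (f in list(rf_selection_frequency, rf_permutation_importance,
                 lasso_scores, elnet_scores))
    expect_true(all(f(X, y, lp) == 0))
})

test_that("selection frequencies sum to the forest's internal-node count", {
  d <- planted_design(n = 80, p = 20, seed = 5)
  lp <- tiny_learner(seed = 5, n_trees = 200)
  sf <- rf_selection_frequency(d$X, d$y, lp)
  expect_true(all(sf >= 0))
  # refit the identical forest (same seed, same settings) and compare
  # against its tree structures: each binary tree has (nodes - 1) / 2
  # internal nodes
  set.seed(lp$seed)
  ref <- randomForest::randomForest(
    x = d$X, y = d$y, ntree = 200, mtry = max(1L, floor(20 / 3)),
    nodesize = 5, importance = TRUE)
  expect_equal(sum(sf), sum((ref$forest$ndbigtree - 1) / 2))
  expect_equal(unname(sf), as.numeric(randomForest::varUsed(ref, count = TRUE)))
  # a marker never chosen for a split has exactly zero permutation importance
  pi_ <- rf_permutation_importance(d$X, d$y, lp)
  unused <- sf == 0
  if (any(unused)) expect_true(all(pi_[unused] == 0))
})

test_that("all four scorers recover a planted single predictor", {
  d <- planted_design(n = 100, p = 50, planted = 7, seed = 2)
  lp <- tiny_learner(seed = 2)
  sf <- rf_selection_frequency(d$X, d$y, lp)
  expect_equal(unname(which.max(sf)), 7)
  expect_gt(sf[7], max(sf[-7]))
  pi_ <- rf_permutation_importance(d$X, d$y, lp)
  expect_equal(unname(which.max(pi_)), 7)
  expect_gt(pi_[7], 0)
  la <- lasso_scores(d$X, d$y, lp)
  expect_equal(unname(which.max(la)), 7)
  expect_lte(sum(la != 0), 5)
  el <- elnet_scores(d$X, d$y, lp)
  expect_equal(unname(which.max(el)), 7)
})

test_that("LASSO concentrates on one of two duplicated markers, ElNet splits", {
  set.seed(21)
  n <- 100
  z <- rbinom(n, 1, 0.5)
  X <- cbind(z, z, matrix(rbinom(n * 8, 1, 0.5), n, 8))
  colnames(X) <- sprintf("M%02d", 1:10)
  y <- z + rnorm(n, 0, 0.2)
  lp <- tiny_learner(seed = 21)
  la <- lasso_scores(X, y, lp)
  pair <- sort(la[1:2], decreasing = TRUE)
  expect_gt(pair[1], 0)
  expect_lte(pair[2], 0.1 * pair[1])
  el <- elnet_scores(X, y, lp)
  pair <- sort(el[1:2], decreasing = TRUE)
  expect_gt(pair[2], 0)
  expect_gte(pair[2] / pair[1], 0.5)
  # grouping effect: the LASSO support never exceeds the Elastic Net's here
  expect_lte(sum(la != 0), sum(el != 0))
})

test_that("per-gene mapping is independent of gene order and deterministic", {
  sim <- simulate_sysgen(sim_params(n_samples = 40, n_genes = 12,
                                    n_chromosomes = 3, n_edges = 20, seed = 14))
  lp <- tiny_learner(seed = 14, n_trees = 60)
  sm <- map_all_genes(sim$genotypes, sim$expression, "LASSO", lp)
  # single gene equals its column
  one <- map_all_genes(sim$genotypes, sim$expression[, 4, drop = FALSE],
                       "LASSO", lp)
  expect_equal(one$values[, 1], sm$values[, 4])
  # permuting genes permutes columns identically
  perm <- sample(ncol(sim$expression))
  smp <- map_all_genes(sim$genotypes, sim$expression[, perm], "LASSO", lp)
  expect_identical(smp$values, sm$values[, perm])
  # identical seeds, identical matrices
  expect_identical(map_all_genes(sim$genotypes, sim$expression, "RF.sf", lp),
                   map_all_genes(sim$genotypes, sim$expression, "RF.sf", lp))
})

test_that("penalized scorers are invariant to marker order", {
  d <- planted_design(n = 60, p = 15, planted = 4, seed = 17)
  lp <- tiny_learner(seed = 17)
  perm <- sample(15)
  for (f in list(lasso_scores, elnet_scores)) {
    base <- f(d$X, d$y, lp)
    shuffled <- f(d$X[, perm], d$y, lp)
    # identical support and ranking; values equal up to solver tolerance
    expect_identical(which(shuffled != 0), which(base[perm] != 0))
    expect_identical(which.max(shuffled), which.max(base[perm]))
    expect_lt(max(abs(as.numeric(shuffled) - as.numeric(base[perm]))), 1e-3)
  }
})

test_that("degenerate sample sizes are handled as specified", {
  set.seed(2)
  X <- matrix(rbinom(40, 1, 0.5), 8, 5)
  y <- rnorm(8)
  expect_warning(lasso_scores(X, y, tiny_learner()), "reducing cv_folds")
  expect_error(rf_selection_frequency(X[1, , drop = FALSE], y[1],
                                      tiny_learner()), "at least 2")
})

test_that("the cross-validated L1 fraction respects the LASSO floor", {
  set.seed(33)
  X <- matrix(rbinom(600, 1, 0.5), 60, 10)
  y <- rnorm(60)   # pure noise: CV favours maximal shrinkage
  lp <- tiny_learner(seed = 33)
  la <- lasso_scores(X, y, lp)
  expect_gte(attr(la, "s"), 0.25)
})
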