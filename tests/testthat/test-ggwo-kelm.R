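test_that("selection fitness combines validation score and subset size", {
  expect_equal(selection_fitness(1, 20, 20, alpha = 0.99), 0.99)
  expect_equal(selection_fitness(0.8, 10, 20, alpha = 0.99), 0.797)
  # strictly decreasing in subset size at fixed score
  f <- sapply(1:20, function(l) selection_fitness(0.9, l, 20))
  expect_true(all(diff(f) < 0))
  # exceeds 0.99 only for a perfect score on a strict subset
  expect_gt(selection_fitness(1, 1, 20, 0.99), 0.99)
  expect_lt(selection_fitness(0.999, 1, 20, 0.99), 0.99 * 0.999 + 0.01)
})

test_that("subset_fitness scores a flagged KELM on a stratified holdout", {
  d <- two_cluster_data(n_per = 30, sep = 8, seed = 21)
  n <- ncol(d$x)
  # separable data, all features: P = 1 so fitness is exactly alpha
  expect_equal(subset_fitness(rep(1, n), d$x, d$y, alpha = 0.99), 0.99)
  expect_error(subset_fitness(rep(0, n), d$x, d$y), "empty feature subset")
  expect_error(subset_fitness(rep(1, 3), d$x, d$y), "flags length")
  # deterministic under the split seed
  set.seed(999)  # optimizer-side stream must not matter
  f1 <- subset_fitness(c(1, 0), d$x, d$y, split_seed = 4)
  f2 <- subset_fitness(c(1, 0), d$x, d$y, split_seed = 4)
  expect_identical(f1, f2)
})

test_that("select_features finds the best subset of a 2-feature exhaustive search", {
  set.seed(30)
  x <- cbind(signal = c(rnorm(30), rnorm(30, 4)), noise = rnorm(60))
  y <- rep(c("a", "b"), each = 30)
  fit <- select_features(x, y, pop_size = 8, max_iter = 30, seed = 13)
  enum <- sapply(list(c(1, 0), c(0, 1), c(1, 1)), function(fl)
    subset_fitness(fl, x, y, split_seed = fit$split_seed))
  expect_equal(fit$fitness, max(enum), tolerance = 1e-12)
  expect_equal(fit$flags, c(1L, 0L))
})

test_that("select_features is reproducible and recovers informative features", {
  task <- make_classification_data(120, 3, 7, class_sep = 3, seed = 42)
  f1 <- select_features(task$x, task$y, max_iter = 25, seed = 17)
  f2 <- select_features(task$x, task$y, max_iter = 25, seed = 17)
  expect_identical(f1$flags, f2$flags)
  expect_identical(f1$fitness, f2$fitness)
  expect_identical(f1$history, f2$history)
  expect_gte(f1$holdout_accuracy, 0.9)
  expect_true(any(which(f1$flags == 1L) %in% task$informative_indices))
  # history of best-so-far fitness is non-decreasing (maximization)
  expect_true(all(diff(f1$history) >= 0))
})

test_that("dropping an exact duplicate column never lowers the best validation score", {
  # the subset-size bonus (N - L) / N is normalized by the total feature
  # count, so the combined fitness shifts mechanically when N changes; the
  # achievable validation accuracy, in contrast, can never improve through
  # a duplicate column (alpha = 1 isolates it)
  set.seed(31)
  x <- cbind(a = c(rnorm(25), rnorm(25, 4)), b = rnorm(50))
  x_dup <- cbind(x, a2 = x[, 1])
  y <- rep(c("u", "v"), each = 25)
  best3 <- max(sapply(1:7, function(k) {
    fl <- as.integer(intToBits(k))[1:3]
    subset_fitness(fl, x_dup, y, alpha = 1, split_seed = 2)
  }))
  best2 <- max(sapply(1:3, function(k) {
    fl <- as.integer(intToBits(k))[1:2]
    subset_fitness(fl, x, y, alpha = 1, split_seed = 2)
  }))
  expect_gte(best2, best3)
})

test_that("hyperparameter tuning fixes a kernel-width-sensitive task", {
  d <- rings_data(seed = 2)
  # fixed enormous gamma: the kernel is flat, classes inseparable
  bad <- subset_fitness(c(1, 1), d$x, d$y, gamma = 1e6, split_seed = 3)
  expect_lt(bad, 0.99 * 0.8)
  fit <- tune_hyperparameters(d$x, d$y, mode = "hyperparams", pop_size = 8,
                              max_iter = 30, split_seed = 3, seed = 23)
  expect_gte(fit$holdout_accuracy, 0.9)
  expect_true(fit$tuned_c >= 2^-5 && fit$tuned_c <= 2^15)
  expect_true(fit$tuned_gamma >= 2^-10 && fit$tuned_gamma <= 2^5)
  expect_equal(fit$n_selected, 2L)  # hyperparams mode keeps all features
})

test_that("degenerate hyperparameter ranges collapse to that single candidate", {
  d <- two_cluster_data(n_per = 15, seed = 24)
  fit <- tune_hyperparameters(d$x, d$y, mode = "hyperparams",
                              c_range = c(32, 32), gamma_range = c(0.5, 0.5),
                              pop_size = 4, max_iter = 3, seed = 3)
  expect_equal(fit$tuned_c, 32)
  expect_equal(fit$tuned_gamma, 0.5)
})

test_that("joint mode searches flags and hyperparameters together", {
  task <- make_classification_data(80, 2, 3, class_sep = 4, seed = 50)
  fit <- ggwo_kelm(task$x, task$y, mode = "joint", pop_size = 6,
                   max_iter = 15, seed = 31)
  expect_gte(fit$n_selected, 1)
  expect_true(fit$tuned_c >= 2^-5 && fit$tuned_c <= 2^15)
  expect_gte(fit$holdout_accuracy, 0.8)
  pred <- predict(fit, task$x)
  expect_equal(length(pred), nrow(task$x))
})

test_that("svd reduction projects onto the top singular directions", {
  set.seed(32)
  x <- matrix(rnorm(40 * 6), 40, 6)
  full <- svd_reduce(x, rank = 6)
  xc <- sweep(x, 2, colMeans(x))
  recon <- full$scores %*% t(full$transform$rotation)
  expect_lt(norm(recon - xc, "F"), 1e-8)

  lowrank <- outer(rnorm(30), rnorm(5))
  r1 <- svd_reduce(lowrank, rank = 1)
  recon1 <- r1$scores %*% t(r1$transform$rotation)
  expect_lt(norm(recon1 - sweep(lowrank, 2, colMeans(lowrank)), "F"), 1e-8)
  expect_equal(ncol(r1$scores), 1)

  expect_equal(svd_project(full$transform, x), full$scores)
  expect_error(svd_reduce(x, 0), "rank out of range")
  expect_error(svd_reduce(x, 7), "rank out of range")
})
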