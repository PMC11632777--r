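test_that("regression metrics match hand-computed cases", {
  m <- regression_metrics(c(0, 1), c(0, 1))
  expect_identical(m$mae, 0)
  expect_identical(m$r2, 1)
  m2 <- regression_metrics(c(0, 2), c(1, 1))
  expect_identical(m2$mae, 1)
  expect_identical(m2$r2, 0)        # 1 - 2/2
  y <- c(1, 5, 2, 8)
  m3 <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m3$r2, 0)
  expect_warning(mz <- regression_metrics(c(3, 3), c(3, 4)),
                 "zero-variance")
  expect_true(is.nan(mz$r2))
  expect_error(regression_metrics(c(1, NA), c(1, 2)), "non-finite")
})

test_that("split plans derive distinct reproducible per-repeat splits", {
  plan <- split_plan(c(0.8, 0.1, 0.1), n_repeats = 4, seed = 7)
  sp1 <- aabba:::split_indices(100, plan$fractions,
                               aabba:::derive_seed(plan$seed, 1))
  sp1b <- aabba:::split_indices(100, plan$fractions,
                                aabba:::derive_seed(plan$seed, 1))
  sp2 <- aabba:::split_indices(100, plan$fractions,
                               aabba:::derive_seed(plan$seed, 2))
  expect_identical(sp1, sp1b)
  expect_false(identical(sp1$test, sp2$test))
  expect_identical(sort(c(sp1$train, sp1$validation, sp1$test)), 1:100)
  expect_length(sp1$train, 80)
  expect_error(split_plan(c(0.5, 0.5, 0.5)), "sum")
  # small-data 20:40:40 split is accepted
  expect_s3_class(split_plan(c(0.2, 0.4, 0.4), 2, 1), "split_plan")
})

test_that("the MLP harness learns a noiseless linear target", {
  bench <- linear_benchmark(n = 500, p = 5, noise = 0)
  rep <- train_mlp(bench$X, bench$y,
                   split_plan(n_repeats = 2, seed = 3),
                   hidden = c(32, 32), max_epochs = 400, patience = 30)
  expect_gte(rep$r2_mean, 0.99)
  expect_s3_class(rep, "model_report")
  expect_identical(nrow(rep$per_repeat), 2L)
  expect_lte(rep$mae_lowest, rep$mae_mean + 1e-12)
})

test_that("degenerate MLP inputs are handled explicitly", {
  bench <- linear_benchmark(n = 60, p = 3)
  expect_warning(
    rep <- train_mlp(bench$X, rep(2, 60), split_plan(n_repeats = 1, seed = 1),
                     hidden = c(8), max_epochs = 30, patience = 5),
    "zero-variance")
  expect_lt(rep$mae_mean, 1)    # predictions near the constant target
  expect_true(is.nan(rep$r2_mean))
  expect_error(train_mlp(bench$X, c(bench$y[-1], NA)), "non-finite")
  expect_error(train_mlp(bench$X[1:10, ], bench$y[1:10]), "at least 20")
})

test_that("GBM relevance is normalized and recovers planted features", {
  set.seed(12)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- 3 * X[, 3] - 2 * X[, 7] + rnorm(n, 0, 0.1)
  res <- train_gbm(X, y, n_estimators = 200, cv_folds = 3, seed = 5)
  expect_equal(sum(res$relevance$relevance), 1, tolerance = 1e-9)
  top3 <- res$relevance$label[order(res$relevance$rank)][1:3]
  expect_true(all(c("f3", "f7") %in% top3))
  expect_s3_class(res$report, "model_report")
  # permuting feature columns permutes relevances with them (up to the
  # backend's histogram-binning noise)
  perm <- c(4, 1, 7, 3, 2, 10, 9, 5, 8, 6)
  res_p <- train_gbm(X[, perm], y, n_estimators = 200, cv_folds = 3, seed = 5)
  rel <- res$relevance$relevance
  names(rel) <- res$relevance$label
  rel_p <- res_p$relevance$relevance
  names(rel_p) <- res_p$relevance$label
  expect_lt(max(abs(rel_p[names(rel)] - rel)), 0.005)
  expect_setequal(res_p$relevance$label[order(res_p$relevance$rank)][1:2],
                  c("f3", "f7"))
})

test_that("duplicating an informative feature splits its relevance", {
  set.seed(13)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * X[, 2] + rnorm(n, 0, 0.1)
  base <- train_gbm(X, y, n_estimators = 150, cv_folds = 3, seed = 9)
  Xd <- cbind(X, f2copy = X[, 2])
  dup <- train_gbm(Xd, y, n_estimators = 150, cv_folds = 3, seed = 9)
  r0 <- base$relevance$relevance[base$relevance$label == "f2"]
  rc <- sum(dup$relevance$relevance[dup$relevance$label %in%
                                      c("f2", "f2copy")])
  expect_gt(rc, 0.5 * r0)
  expect_lt(rc, 2 * r0)
})

test_that("the GP kernel and harness behave analytically", {
  # analytic point evaluations
  expect_identical(gp_kernel(c(0, 0), c(0, 0)), 0)
  expect_equal(gp_kernel(c(1, 1), c(1, 1)), 2)
  # linear-kernel limit for large length-scales
  x1 <- c(1, 2, 3); x2 <- c(0.5, -1, 2)
  lim <- gp_kernel(x1, x2, length_scale = 1e3 * sqrt(sum((x1 - x2)^2)))
  expect_equal(lim, sum(x1 * x2), tolerance = 1e-6)
  expect_error(gp_kernel(c(1, 2), c(1, 2, 3)), "dimension mismatch")
  # Gram symmetry and PSD after jitter on random inputs
  set.seed(21)
  X <- matrix(rnorm(40 * 3), 40, 3)
  K <- gp_kernel(X, X, variance_linear = 0.7, variance_rbf = 1.3,
                 length_scale = 2)
  expect_equal(K, t(K), tolerance = 1e-12)
  cj <- aabba:::chol_jitter(K)
  ev <- eigen(K + diag(cj$jitter, nrow(K)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("the GP harness nails a noiseless linear target", {
  bench <- linear_benchmark(n = 200, p = 4, noise = 0)
  rep <- train_gp(bench$X, bench$y, split_plan(n_repeats = 2, seed = 11),
                  n_restarts = 2, maxit = 40)
  expect_lt(rep$mae_mean, 0.01 * sd(bench$y))
  expect_gt(rep$r2_mean, 0.999)
})

test_that("the GP tolerates duplicate rows and ignores column order", {
  bench <- linear_benchmark(n = 80, p = 3, noise = 0.05)
  X <- bench$X
  X[2, ] <- X[1, ]                     # exact duplicate row
  rep <- train_gp(X, bench$y, split_plan(n_repeats = 1, seed = 2),
                  n_restarts = 1, maxit = 25)
  expect_true(is.finite(rep$mae_mean))
  perm <- c(3, 1, 2)
  rep_p <- train_gp(X[, perm], bench$y, split_plan(n_repeats = 1, seed = 2),
                    n_restarts = 1, maxit = 25)
  expect_equal(rep_p$mae_mean, rep$mae_mean, tolerance = 1e-6)
})

test_that("GP marginal-likelihood gradients match finite differences", {
  set.seed(31)
  X <- matrix(rnorm(25 * 2), 25, 2)
  y <- rnorm(25)
  G <- tcrossprod(X)
  sq <- pmax(outer(diag(G), diag(G), "+") - 2 * G, 0)
  th <- c(0.3, 0.5, -1)
  an <- aabba:::gp_nll(th, G, sq, y)$gradient
  for (i in 1:3) {
    h <- 1e-6
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    fd <- (aabba:::gp_nll(tp, G, sq, y)$value -
             aabba:::gp_nll(tm, G, sq, y)$value) / (2 * h)
    expect_equal(an[i], fd, tolerance = 1e-4)
  }
})

test_that("all three harnesses resolve the planted benchmark to r2 >= 0.9", {
  bm <- planted_benchmark()
  cols <- c(bm$planted, sprintf("noise%03d", 1:48))   # 2 planted + 48 noise
  X <- bm$X[, cols]
  gbm <- train_gbm(X, bm$y, n_estimators = 300, cv_folds = 3, seed = 71)
  expect_gte(gbm$report$r2_mean, 0.9)
  gp <- train_gp(X, bm$y, split_plan(n_repeats = 1, seed = 72),
                 n_restarts = 1, maxit = 30)
  expect_gte(gp$r2_mean, 0.9)
  mlp <- train_mlp(X, bm$y, split_plan(n_repeats = 1, seed = 73),
                   hidden = c(64, 64), max_epochs = 800, patience = 100,
                   learning_rate = 5e-3)
  expect_gte(mlp$r2_mean, 0.9)
})
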