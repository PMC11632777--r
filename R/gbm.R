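#' Gradient-boosting regression with impurity-based feature relevance
#'
#' A gradient-boosted ensemble of regression trees (xgboost backend)
#' minimizing squared error, evaluated by k-fold cross-validation.  The
#' default configuration is 1000 trees of maximum depth 5, learning rate
#' 0.05, 5 folds.  Feature relevance is the fraction of the ensemble's total
#' squared-error impurity reduction (split gain, the Friedman mean-squared-
#' error criterion) attributable to splits on each feature, averaged over
#' folds and normalized to sum to 1; features never split on score 0.
#'
#' @param X numeric feature matrix with column labels.
#' @param y numeric targets.
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment and tree fitting.
#' @param nthread threads passed to xgboost (default 1 for reproducibility).
#' @return List with `report` (a `model_report`; one "repeat" per fold) and
#'   `relevance` (a `relevance_table`: data.frame of `label`, `relevance`,
#'   `rank`, ordered as the columns of `X`).
#' @export
train_gbm <- function(X, y, n_estimators = 1000L, max_depth = 5L,
                      learning_rate = 0.05, cv_folds = 5L, seed = 1L,
                      nthread = 1L) {
  check_xy(X, y)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  params <- list(objective = "reg:squarederror", max_depth = max_depth,
                 eta = learning_rate, nthread = nthread,
                 tree_method = "hist", seed = seed)
  gain <- matrix(0, ncol(X), cv_folds, dimnames = list(colnames(X), NULL))
  reps <- lapply(seq_len(cv_folds), function(k) {
    tr <- folds != k
    dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = n_estimators, verbose = 0)
    pred <- stats::predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
    imp <- xgboost::xgb.importance(model = fit)
    if (!is.null(imp) && nrow(imp))
      gain[imp$Feature, k] <<- imp$Gain
    m <- regression_metrics(y[!tr], pred)
    data.frame(repeat_ = k, mae = m$mae, r2 = m$r2)
  })
  rel <- rowMeans(gain)
  tot <- sum(rel)
  rel <- if (tot > 0) rel / tot else rep(1 / length(rel), length(rel))
  list(report = new_model_report(do.call(rbind, reps), "gbm",
         list(n_estimators = n_estimators, max_depth = max_depth,
              learning_rate = learning_rate, cv_folds = cv_folds,
              seed = seed)),
       relevance = relevance_table(colnames(X), rel))
}

#' Construct a feature-relevance table
#'
#' @param labels feature labels in original column order.
#' @param relevance non-negative fractions; normalized to sum to 1.
#' @return A data.frame of class `relevance_table` with columns `label`,
#'   `relevance` and `rank` (1 = most relevant; ties broken by original
#'   column order).
#' @export
relevance_table <- function(labels, relevance) {
  stopifnot(length(labels) == length(relevance), all(relevance >= 0))
  tot <- sum(relevance)
  if (abs(tot - 1) > 1e-9) {
    if (tot == 0) stop("all-zero relevance")
    relevance <- relevance / tot
  }
  ord <- order(-relevance, seq_along(relevance))
  rank <- integer(length(relevance))
  rank[ord] <- seq_along(ord)
  structure(data.frame(label = as.character(labels),
                       relevance = as.numeric(relevance), rank = rank,
                       stringsAsFactors = FALSE),
            class = c("relevance_table", "data.frame"))
}
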