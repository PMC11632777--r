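#' Prune features by accumulated relevance
#'
#' Keeps the smallest prefix of the relevance ranking whose cumulative
#' relevance reaches `threshold` (ties in relevance broken by original
#' column order).  The kept set is reported in original column order so that
#' pruning at threshold 1 is the identity.
#'
#' @param rel a `relevance_table` (see [relevance_table()]).
#' @param threshold fraction in (0, 1].
#' @return List of class `prune_result` with `kept` (labels, original
#'   order), `accumulated_relevance` (achieved fraction) and `dimension`.
#' @examples
#' rel <- relevance_table(c("a", "b", "c"), c(0.5, 0.3, 0.2))
#' prune_by_accumulated_relevance(rel, 0.8)  # keeps a, b
#' @export
prune_by_accumulated_relevance <- function(rel, threshold) {
  stopifnot(inherits(rel, "relevance_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a fraction in (0, 1]")
  ord <- order(rel$rank)
  csum <- cumsum(rel$relevance[ord])
  k <- which(csum >= threshold - 1e-12)[1L]
  if (is.na(k)) k <- length(ord)          # numerical slack at threshold 1
  sel <- sort(ord[seq_len(k)])            # back to original column order
  structure(list(kept = rel$label[sel],
                 accumulated_relevance = csum[k],
                 dimension = k),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat("prune_result: ", x$dimension, " features kept (accumulated relevance ",
      sprintf("%.3f", x$accumulated_relevance), ")\n", sep = "")
  invisible(x)
}

#' MAE-versus-dimensionality pruning scan
#'
#' Starting from the full feature matrix and a relevance ranking (typically
#' from [train_gbm()]), trains one model per accumulated-relevance threshold
#' on the pruned columns and tabulates MAE and r2 against the reduced
#' dimensionality.  The full-dimensional baseline is always included as the
#' first row (threshold `NA`), and the relevance ranking is computed once,
#' not re-estimated per threshold.
#'
#' For the GP the kernel hyperparameters are by default fitted once per
#' repeat on the full-dimensional data and reused across thresholds
#' (`refit = "once"`), which makes the threshold-1 row identical to the
#' baseline; `refit = "per_threshold"` re-optimizes them on each pruned set.
#' The MLP is always retrained per threshold.
#'
#' @param X numeric feature matrix with labels matching `rel$label`.
#' @param y numeric targets.
#' @param rel a `relevance_table` over the columns of `X`.
#' @param thresholds decreasing fractions in (0, 1]; default a 100%..10%
#'   grid in steps of 10%.
#' @param model `"gp"` or `"mlp"`.
#' @param plan a [split_plan].
#' @param refit GP hyperparameter policy (see above).
#' @param ... passed to [train_gp()] or [train_mlp()].
#' @return data.frame of class `reduce_scan` with columns `threshold`,
#'   `dimension`, `mae_mean`, `mae_sd`, `r2_mean`, `r2_sd`.
#' @export
reduce_scan <- function(X, y, rel, thresholds = seq(1, 0.1, by = -0.1),
                        model = c("gp", "mlp"), plan = split_plan(),
                        refit = c("once", "per_threshold"), ...) {
  model <- match.arg(model)
  refit <- match.arg(refit)
  stopifnot(inherits(rel, "relevance_table"),
            identical(rel$label, colnames(X)))
  if (any(diff(thresholds) > 0)) stop("thresholds must be sorted descending")
  runner <- make_scan_runner(X, y, model, plan, refit, ...)
  rows <- list(scan_row(NA_real_, ncol(X), runner(colnames(X))))
  for (th in thresholds) {
    pr <- prune_by_accumulated_relevance(rel, th)
    rows[[length(rows) + 1L]] <- scan_row(th, pr$dimension, runner(pr$kept))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reduce_scan", "data.frame")
  out
}

scan_row <- function(threshold, dimension, report) {
  data.frame(threshold = threshold, dimension = dimension,
             mae_mean = report$mae_mean, mae_sd = report$mae_sd,
             r2_mean = report$r2_mean, r2_sd = report$r2_sd)
}

make_scan_runner <- function(X, y, model, plan, refit, ...) {
  if (model == "mlp")
    return(function(cols) train_mlp(X[, cols, drop = FALSE], y, plan, ...))
  if (refit == "per_threshold")
    return(function(cols) train_gp(X[, cols, drop = FALSE], y, plan, ...))
  # fixed-hyperparameter GP: fit theta once per repeat on all columns
  n <- nrow(X)
  dots <- list(...)
  n_restarts <- dots$n_restarts %||% 3L
  maxit <- dots$maxit %||% 50L
  repeat_state <- lapply(seq_len(plan$n_repeats), function(k) {
    sp <- split_indices(n, plan$fractions, derive_seed(plan$seed, k))
    zs <- standardizer(X[sp$train, , drop = FALSE])
    fit <- gp_fit(zs(X[c(sp$train, sp$validation), , drop = FALSE]),
                  y[c(sp$train, sp$validation)], n_restarts = n_restarts,
                  seed = derive_seed(plan$seed, 2000L + k), maxit = maxit)
    list(split = sp, theta = fit[c("amp", "length_scale", "noise")])
  })
  function(cols) {
    reps <- lapply(seq_along(repeat_state), function(k) {
      st <- repeat_state[[k]]
      sp <- st$split
      Xs <- X[, cols, drop = FALSE]
      zs <- standardizer(Xs[sp$train, , drop = FALSE])
      fitidx <- c(sp$train, sp$validation)
      Xf <- zs(Xs[fitidx, , drop = FALSE])
      yc <- y[fitidx] - mean(y[fitidx])
      K <- st$theta$amp * tcrossprod(Xf) *
        exp(-as.matrix(stats::dist(Xf))^2 / (2 * st$theta$length_scale^2)) +
        diag(st$theta$noise, length(fitidx))
      cj <- chol_jitter(K)
      alpha <- backsolve(cj$L, forwardsolve(t(cj$L), yc))
      fit <- list(X = Xf, alpha = alpha, length_scale = st$theta$length_scale,
                  y_mu = mean(y[fitidx]),
                  params = list(variance_linear = sqrt(st$theta$amp),
                                variance_rbf = sqrt(st$theta$amp),
                                length_scale = st$theta$length_scale))
      pred <- gp_predict(fit, zs(Xs[sp$test, , drop = FALSE]))
      m <- regression_metrics(y[sp$test], pred)
      data.frame(repeat_ = k, mae = m$mae, r2 = m$r2)
    })
    new_model_report(do.call(rbind, reps), "gp_fixed", list())
  }
}
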