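#' Regression metrics: mean absolute error and coefficient of determination
#'
#' `r2` is the coefficient of determination `1 - SS_res / SS_tot` (not the
#' squared Pearson correlation); predicting the mean of `y_true` therefore
#' scores exactly 0, and `r2` is reported as `NaN` with a warning when
#' `y_true` has zero variance.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return List with elements `mae` and `r2`.
#' @examples
#' regression_metrics(c(0, 2), c(1, 1))  # mae 1, r2 0
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred)))
    stop("non-finite values in targets or predictions")
  mae <- mean(abs(y_true - y_pred))
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("zero-variance target: r2 is undefined (NaN)")
    return(list(mae = mae, r2 = NaN))
  }
  list(mae = mae, r2 = 1 - sum((y_true - y_pred)^2) / ss_tot)
}

#' Repeated train/validation/test split plan
#'
#' @param fractions train/validation/test fractions summing to 1 (default
#'   80:10:10; 20:40:40 is the conventional small-data setting).
#' @param n_repeats number of independent repetitions.
#' @param seed integer master seed; each repeat uses a distinct seed derived
#'   from it.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(fractions = c(0.8, 0.1, 0.1), n_repeats = 10,
                       seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8, n_repeats >= 1L)
  structure(list(fractions = fractions, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_plan")
}

# distinct sub-seeds, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

# deterministic shuffle split into train/val/test index lists
split_indices <- function(n, fractions, seed) {
  ord <- with_seed(seed, sample.int(n))
  n_tr <- max(1L, round(fractions[1L] * n))
  n_va <- max(1L, round(fractions[2L] * n))
  n_tr <- min(n_tr, n - 2L)
  n_va <- min(n_va, n - n_tr - 1L)
  list(train = ord[seq_len(n_tr)],
       validation = ord[n_tr + seq_len(n_va)],
       test = ord[(n_tr + n_va + 1L):n])
}

# run thunk under a temporary RNG state; global .Random.seed is restored
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# column-wise z-score using train-set statistics; sd 0 -> column left centered
standardizer <- function(X_train) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  function(X) sweep(sweep(X, 2L, mu), 2L, sdv, "/")
}

new_model_report <- function(per_repeat, model, config = list()) {
  best <- which.min(per_repeat$mae)
  structure(list(
    model = model,
    mae_mean = mean(per_repeat$mae), mae_sd = stats::sd(per_repeat$mae),
    r2_mean = mean(per_repeat$r2), r2_sd = stats::sd(per_repeat$r2),
    mae_lowest = per_repeat$mae[best], r2_at_lowest = per_repeat$r2[best],
    per_repeat = per_repeat, config = config),
    class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("model_report (", x$model, ", ", nrow(x$per_repeat), " repeats)\n",
      sep = "")
  cat(sprintf("  MAE: %.4g +/- %.2g   (lowest %.4g)\n",
              x$mae_mean, x$mae_sd, x$mae_lowest))
  cat(sprintf("  r2:  %.4g +/- %.2g   (at lowest-MAE repeat %.4g)\n",
              x$r2_mean, x$r2_sd, x$r2_at_lowest))
  invisible(x)
}

check_xy <- function(X, y, min_n = 20L) {
  stopifnot(is.matrix(X), is.numeric(y))
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nrow(X) < min_n) stop("need at least ", min_n, " rows")
  if (!all(is.finite(X))) stop("non-finite feature values")
  if (!all(is.finite(y))) stop("non-finite target values")
  invisible(TRUE)
}
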