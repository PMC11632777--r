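#' Multilayer-perceptron regression over repeated splits
#'
#' A feed-forward network with ReLU hidden layers (default two of 128 units)
#' trained with Adam on the mean-squared-error loss.  Per repeat of the
#' split plan: features are z-scored on the training set only, training runs
#' with early stopping on validation MSE, and test-set MAE/r2 are recorded;
#' the repeats are aggregated as mean +/- sd plus the lowest-MAE repeat.
#'
#' Epoch budget, patience and batch size are not fixed by the architecture
#' convention; the defaults (2000 epochs max, patience 50, batch
#' `min(64, n/10)`) are package choices and configurable.
#'
#' @param X numeric feature matrix (labeled columns).
#' @param y numeric targets.
#' @param plan a [split_plan].
#' @param hidden integer vector of hidden-layer widths.
#' @param max_epochs,patience early-stopping budget on validation MSE.
#' @param batch_size minibatch size (default `min(64, floor(n/10))`).
#' @param learning_rate Adam step size.
#' @return A `model_report` (see [regression_metrics()] for the metric
#'   definitions).
#' @export
train_mlp <- function(X, y, plan = split_plan(), hidden = c(128L, 128L),
                      max_epochs = 2000L, patience = 50L,
                      batch_size = NULL, learning_rate = 1e-3) {
  check_xy(X, y)
  n <- nrow(X)
  if (is.null(batch_size)) batch_size <- max(1L, min(64L, floor(n / 10)))
  reps <- lapply(seq_len(plan$n_repeats), function(k) {
    sp <- split_indices(n, plan$fractions, derive_seed(plan$seed, k))
    zs <- standardizer(X[sp$train, , drop = FALSE])
    net <- mlp_fit(zs(X[sp$train, , drop = FALSE]), y[sp$train],
                   zs(X[sp$validation, , drop = FALSE]), y[sp$validation],
                   hidden, max_epochs, patience, batch_size, learning_rate,
                   seed = derive_seed(plan$seed, 1000L + k))
    pred <- mlp_predict(net, zs(X[sp$test, , drop = FALSE]))
    m <- regression_metrics(y[sp$test], pred)
    data.frame(repeat_ = k, mae = m$mae, r2 = m$r2)
  })
  new_model_report(do.call(rbind, reps), "mlp",
                  list(hidden = hidden, max_epochs = max_epochs,
                       patience = patience, batch_size = batch_size,
                       learning_rate = learning_rate, plan = unclass(plan)))
}

# He-initialized fully connected net; returns list of W (with bias row)
mlp_init <- function(sizes, seed) {
  with_seed(seed, lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    rbind(matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                              sqrt(2 / fan_in)), fan_in),
          0)                                  # bias row
  }))
}

mlp_forward <- function(W, X) {
  acts <- vector("list", length(W) + 1L)
  acts[[1L]] <- X
  A <- X
  for (l in seq_along(W)) {
    Z <- cbind(A, 1) %*% W[[l]]
    A <- if (l < length(W)) pmax(Z, 0) else Z   # ReLU hidden, linear output
    acts[[l + 1L]] <- A
  }
  acts
}

mlp_fit <- function(X, y, Xval, yval, hidden, max_epochs, patience,
                    batch_size, lr, seed) {
  sizes <- c(ncol(X), hidden, 1L)
  W <- mlp_init(sizes, seed)
  mom <- lapply(W, function(w) w * 0)
  vel <- lapply(W, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  y_mu <- mean(y); y_sd <- stats::sd(y); if (y_sd == 0) y_sd <- 1
  yt <- (y - y_mu) / y_sd
  yv <- (yval - y_mu) / y_sd
  n <- nrow(X)
  best <- list(W = W, val = Inf, wait = 0L)
  step <- 0L
  batch_plan <- with_seed(seed + 1L, lapply(seq_len(max_epochs), function(e)
    sample.int(n)))
  for (epoch in seq_len(max_epochs)) {
    ord <- batch_plan[[epoch]]
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acts <- mlp_forward(W, X[idx, , drop = FALSE])
      nb <- length(idx)
      delta <- 2 * (acts[[length(acts)]] - yt[idx]) / nb     # dMSE/dout
      grads <- vector("list", length(W))
      for (l in rev(seq_along(W))) {
        A_in <- acts[[l]]
        grads[[l]] <- crossprod(cbind(A_in, 1), delta)
        if (l > 1L) {
          back <- delta %*% t(W[[l]][-nrow(W[[l]]), , drop = FALSE])
          delta <- back * (acts[[l]] > 0)                    # ReLU gradient
        }
      }
      step <- step + 1L
      for (l in seq_along(W)) {
        mom[[l]] <- beta1 * mom[[l]] + (1 - beta1) * grads[[l]]
        vel[[l]] <- beta2 * vel[[l]] + (1 - beta2) * grads[[l]]^2
        mhat <- mom[[l]] / (1 - beta1^step)
        vhat <- vel[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_pred <- mlp_forward(W, Xval)[[length(W) + 1L]]
    val_mse <- mean((val_pred - yv)^2)
    if (val_mse < best$val - 1e-12) {
      best <- list(W = W, val = val_mse, wait = 0L)
    } else {
      best$wait <- best$wait + 1L
      if (best$wait >= patience) break
    }
  }
  list(W = best$W, y_mu = y_mu, y_sd = y_sd, val_mse = best$val)
}

mlp_predict <- function(net, X) {
  out <- mlp_forward(net$W, X)[[length(net$W) + 1L]]
  as.vector(out) * net$y_sd + net$y_mu
}
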