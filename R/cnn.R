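# ---------------------------------------------------------------------------
# 3D-CNN joint-angle decoder. Architecture: one 3D convolutional layer (ReLU)
# with stride 1 and same-size zero padding, max-pooling (2x2x2, stride 1,
# same padding), flatten, one hidden fully connected layer (ReLU), one linear
# output neuron. One network is trained per joint.
# ---------------------------------------------------------------------------

#' 3D-CNN decoder configuration
#'
#' Defaults are the published training regime: 70 filters of size 7 x 6 x 8,
#' 2 x 2 x 2 max-pooling with stride 1, SGD with momentum 0.75, L2 weight
#' regularization 0.3, mini-batches of 128 and 10 epochs. The hidden layer
#' width and learning rate are not dictated by that regime and default to 64
#' and 0.01. For desk-scale test fixtures a smaller `n_filters`/`hidden`
#' keeps training within CPU budgets (see the methods vignette).
#'
#' @param n_filters Number of convolution filters.
#' @param filter_size Length-3 filter size over (channel, lag, feature).
#' @param pool_size Length-3 max-pool window.
#' @param hidden Hidden fully connected layer width.
#' @param l2 L2 weight-regularization coefficient.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param learning_rate SGD learning rate.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 70, filter_size = c(7, 6, 8),
                       pool_size = c(2, 2, 2), hidden = 64, l2 = 0.3,
                       momentum = 0.75, batch_size = 128, epochs = 10,
                       learning_rate = 0.01, seed = 0) {
  stopifnot(n_filters >= 1, length(filter_size) == 3, length(pool_size) == 3,
            hidden >= 1, batch_size >= 1, epochs >= 1, learning_rate > 0)
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  structure(list(n_filters = as.integer(n_filters),
                 filter_size = as.integer(filter_size),
                 pool_size = as.integer(pool_size),
                 hidden = as.integer(hidden), l2 = l2, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# Flatten (channel, lag, feature, time) tensors to S x N with channel fastest.
tensor_to_matrix <- function(fts) {
  d <- dim(fts)
  matrix(as.numeric(fts), nrow = prod(d[1:3]), ncol = d[4])
}

# per-(channel, feature) normalization statistics over lags and time
tensor_norm_stats <- function(fts) {
  d <- dim(fts)
  mu <- matrix(0, d[1], d[3])
  sd_ <- matrix(1, d[1], d[3])
  for (f in seq_len(d[3])) for (c_i in seq_len(d[1])) {
    v <- fts[c_i, , f, ]
    mu[c_i, f] <- mean(v)
    s <- stats::sd(v)
    sd_[c_i, f] <- if (is.finite(s) && s > 1e-12) s else 1
  }
  list(mu = mu, sd = sd_)
}

apply_tensor_norm <- function(fts, stats) {
  d <- dim(fts)
  out <- fts
  for (f in seq_len(d[3])) for (c_i in seq_len(d[1]))
    out[c_i, , f, ] <- (fts[c_i, , f, ] - stats$mu[c_i, f]) / stats$sd[c_i, f]
  out
}

cnn_init_weights <- function(dims, config) {
  S <- prod(dims)
  nk <- prod(config$filter_size)
  f <- config$n_filters
  h <- config$hidden
  list(
    Wc = matrix(stats::rnorm(f * nk, sd = sqrt(2 / nk)), f, nk),
    bc = rep(0, f),
    W1 = matrix(stats::rnorm(h * f * S, sd = sqrt(2 / (f * S))), h, f * S),
    b1 = rep(0, h),
    # zero-initialized output layer: training starts at the mean predictor
    # and avoids the unstable early phase a random read-out produces
    W2 = matrix(0, 1, h),
    b2 = 0
  )
}

#' Train the 3D-CNN decoder for one joint
#'
#' Features are z-scored per (channel, feature) and the target z-scored, both
#' using statistics of the data passed here (the training fold), so no test
#' information leaks in. Training minimizes mean squared error plus an L2
#' weight penalty by SGD with momentum. Identical configuration and seed give
#' identical models.
#'
#' @param features A `feature_tensor_series` (training fold).
#' @param target Numeric vector of the joint angle at the tensor times.
#' @param config A [cnn_config()].
#' @param track_loss If `TRUE`, record the full training-set MSE after every
#'   epoch (otherwise only before/after training).
#' @return An object of class `cnn_decoder`.
#' @export
train_cnn <- function(features, target, config = cnn_config(),
                      track_loss = FALSE) {
  d <- dim(features)
  if (length(target) != d[4])
    stop("target length does not match the tensor series")
  nstats <- tensor_norm_stats(features)
  Xn <- apply_tensor_norm(features, nstats)
  X <- tensor_to_matrix(Xn)
  y_mu <- mean(target)
  y_sd <- stats::sd(target)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  y <- (target - y_mu) / y_sd
  n <- length(y)
  res <- withr::with_seed(config$seed, {
    init <- cnn_init_weights(d[1:3], config)
    ord <- t(vapply(seq_len(config$epochs), function(e) sample.int(n),
                    integer(n)))
    .cnn_train_cpp(X, y, as.integer(d[1:3]), config$filter_size,
                   config$pool_size, init, ord, config$batch_size,
                   config$learning_rate, config$momentum, config$l2,
                   isTRUE(track_loss))
  })
  structure(list(weights = res$weights, loss = res$loss, dims = d[1:3],
                 config = config, norm = nstats,
                 y_center = y_mu, y_scale = y_sd),
            class = "cnn_decoder")
}

#' Predict joint angles with a trained 3D-CNN decoder
#'
#' @param object A `cnn_decoder` from [train_cnn()].
#' @param features A `feature_tensor_series` with the training geometry.
#' @param ... Unused.
#' @return Numeric vector of predicted angles (degrees).
#' @export
predict.cnn_decoder <- function(object, features, ...) {
  d <- dim(features)
  if (!all(d[1:3] == object$dims))
    stop("tensor geometry does not match the trained model")
  Xn <- apply_tensor_norm(features, object$norm)
  X <- tensor_to_matrix(Xn)
  yh <- .cnn_predict_cpp(X, as.integer(object$dims), object$config$filter_size,
                         object$config$pool_size, object$weights)
  yh * object$y_scale + object$y_center
}

# Reference forward pass in plain R, used by the test suite as an independent
# oracle for the C++ implementation.
cnn_forward_reference <- function(tensor, weights, filter_size, pool_size) {
  d <- dim(tensor)
  f_n <- nrow(weights$Wc)
  pad <- (filter_size - 1) %/% 2
  conv <- array(0, dim = c(d, f_n))
  for (ff in seq_len(f_n)) {
    W <- array(weights$Wc[ff, ], dim = filter_size)
    for (kf in seq_len(d[3])) for (l in seq_len(d[2])) for (c_i in seq_len(d[1])) {
      acc <- 0
      for (zf in seq_len(filter_size[3])) for (zl in seq_len(filter_size[2]))
        for (zc in seq_len(filter_size[1])) {
          jc <- c_i + zc - 1 - pad[1]; jl <- l + zl - 1 - pad[2]
          jf <- kf + zf - 1 - pad[3]
          if (jc >= 1 && jc <= d[1] && jl >= 1 && jl <= d[2] &&
              jf >= 1 && jf <= d[3])
            acc <- acc + W[zc, zl, zf] * tensor[jc, jl, jf]
        }
      conv[c_i, l, kf, ff] <- max(acc + weights$bc[ff], 0)
    }
  }
  pooled <- array(0, dim = dim(conv))
  for (ff in seq_len(f_n)) for (kf in seq_len(d[3])) for (l in seq_len(d[2]))
    for (c_i in seq_len(d[1])) {
      vals <- c()
      for (zf in 0:(pool_size[3] - 1)) for (zl in 0:(pool_size[2] - 1))
        for (zc in 0:(pool_size[1] - 1)) {
          jc <- c_i + zc; jl <- l + zl; jf <- kf + zf
          if (jc <= d[1] && jl <= d[2] && jf <= d[3])
            vals <- c(vals, conv[jc, jl, jf, ff])
        }
      pooled[c_i, l, kf, ff] <- max(vals)
    }
  flat <- as.numeric(pooled)
  h1 <- pmax(as.numeric(weights$W1 %*% flat) + weights$b1, 0)
  as.numeric(weights$W2 %*% h1) + weights$b2
}
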