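# ---------------------------------------------------------------------------
# Decoder evaluation: R^2 score (percent), contiguous threefold cross-
# validation, channel-subset selection, and the linear baselines (PLS, Lasso).
# ---------------------------------------------------------------------------

#' Coefficient of determination, in percent
#'
#' `R2 = (1 - sum((y - yhat)^2) / sum((y - mean(y))^2)) * 100`. May be
#' negative for predictors worse than the mean; never exceeds 100.
#'
#' @param y Measured series.
#' @param yhat Estimated series of the same length.
#' @return R-squared in percent.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least two data points")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) stop("R^2 is undefined for a constant measured series")
  (1 - sum((y - yhat)^2) / ss_tot) * 100
}

#' Contiguous cross-validation folds
#'
#' Lagged features overlap in time, so folds are contiguous temporal blocks
#' (shuffled samples would leak across train/test).
#'
#' @param n Number of time points.
#' @param k Number of folds (default 3).
#' @return Integer vector of fold labels, blocks as equal as possible.
#' @export
cv_folds <- function(n, k = 3) {
  if (n < 2 * k) stop(sprintf("too few samples (%d) for %d folds", n, k))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(k), times = sizes)
}

#' Channel subsets used in the column/side comparisons
#'
#' `lateral` = electrodes 1, 4, 5, 8; `dorsal` = 2, 3, 6, 7; `left` = 3, 4,
#' 7, 8; `right` = 1, 2, 5, 6; `all` keeps every electrode.
#'
#' @param subset Subset label.
#' @param channel_map Channel map data frame (default [default_channel_map()]).
#' @return Electrode numbers in ascending order.
#' @export
subset_electrodes <- function(subset = c("all", "lateral", "dorsal", "left",
                                         "right"),
                              channel_map = default_channel_map()) {
  subset <- match.arg(subset)
  sel <- switch(subset,
    all = channel_map$electrode,
    lateral = channel_map$electrode[channel_map$column == "lateral"],
    dorsal = channel_map$electrode[channel_map$column == "dorsal"],
    left = channel_map$electrode[channel_map$side == "left"],
    right = channel_map$electrode[channel_map$side == "right"])
  sort(sel)
}

#' Restrict a feature tensor series to a channel subset
#'
#' @param fts A `feature_tensor_series`.
#' @param subset One of `"all"`, `"lateral"`, `"dorsal"`, `"left"`, `"right"`.
#' @param channel_map Channel map with one row per tensor channel.
#' @return A reduced `feature_tensor_series` (channels in original order).
#' @export
subset_channels <- function(fts, subset = "all",
                            channel_map = default_channel_map()) {
  electrodes <- subset_electrodes(subset, channel_map)
  rows <- which(channel_map$electrode %in% electrodes)
  out <- fts[rows, , , , drop = FALSE]
  structure(out, t = attr(fts, "t"), class = "feature_tensor_series",
            electrodes = channel_map$electrode[rows])
}

# N x (C*L*F) design matrix for the linear baselines
flatten_features <- function(fts) {
  d <- dim(fts)
  t(matrix(as.numeric(fts), nrow = prod(d[1:3]), ncol = d[4]))
}

# --- PLS1 (NIPALS) -----------------------------------------------------------

pls_fit_raw <- function(X, y, ncomp) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  p <- ncol(X)
  ncomp <- min(ncomp, p, nrow(X) - 1)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1; break }
    w <- w / nw
    t_s <- Xc %*% w
    tt <- sum(t_s^2)
    pv <- crossprod(Xc, t_s) / tt
    qv <- sum(yc * t_s) / tt
    Xc <- Xc - t_s %*% t(pv)
    yc <- yc - t_s * qv
    W[, a] <- w; P[, a] <- pv; q[a] <- qv
  }
  if (ncomp == 0) return(list(coef = rep(0, p), intercept = ym, ncomp = 0))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), q)
  list(coef = as.numeric(B), intercept = ym - sum(xm * B), ncomp = ncomp)
}

pls_predict_raw <- function(fit, X) as.numeric(X %*% fit$coef) + fit$intercept

#' Fit a linear baseline decoder (PLS or Lasso)
#'
#' Feature tensors are flattened to vectors. Hyperparameters (PLS component
#' count; Lasso penalty) are chosen by an inner contiguous k-fold
#' cross-validation on the training data only.
#'
#' @param features A `feature_tensor_series` (training fold).
#' @param target Numeric target vector.
#' @param method `"pls"` or `"lasso"`.
#' @param inner_k Inner CV folds (default 3).
#' @param ncomp_grid Candidate PLS component counts.
#' @return An object of class `baseline_decoder`.
#' @export
fit_baseline <- function(features, target, method = c("pls", "lasso"),
                         inner_k = 3, ncomp_grid = c(1, 2, 3, 5, 8, 12, 20)) {
  method <- match.arg(method)
  X <- if (inherits(features, "feature_tensor_series"))
    flatten_features(features) else as.matrix(features)
  y <- as.numeric(target)
  if (nrow(X) != length(y)) stop("features and target are misaligned")
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) stop("features are constant; nothing to fit")
  fold <- cv_folds(nrow(X), inner_k)
  if (method == "pls") {
    ncomp_grid <- ncomp_grid[ncomp_grid <= min(ncol(X), nrow(X) - 1)]
    press <- vapply(ncomp_grid, function(nc) {
      s <- 0
      for (f in seq_len(inner_k)) {
        tr <- fold != f
        fit <- pls_fit_raw(X[tr, , drop = FALSE], y[tr], nc)
        s <- s + sum((y[!tr] - pls_predict_raw(fit, X[!tr, , drop = FALSE]))^2)
      }
      s
    }, numeric(1))
    best <- ncomp_grid[which.min(press)]
    fit <- pls_fit_raw(X, y, best)
    out <- list(method = "pls", fit = fit, ncomp = fit$ncomp)
  } else {
    fit0 <- glmnet::glmnet(X, y, alpha = 1)
    lambdas <- fit0$lambda
    err <- matrix(0, inner_k, length(lambdas))
    for (f in seq_len(inner_k)) {
      tr <- fold != f
      fitf <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], alpha = 1,
                             lambda = lambdas)
      pred <- stats::predict(fitf, X[!tr, , drop = FALSE])
      # pad if the path terminated early
      if (ncol(pred) < length(lambdas))
        pred <- cbind(pred, matrix(pred[, ncol(pred)], nrow(pred),
                                   length(lambdas) - ncol(pred)))
      err[f, ] <- colMeans((pred - y[!tr])^2)
    }
    best <- lambdas[which.min(colMeans(err))]
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambdas)
    out <- list(method = "lasso", fit = fit, lambda = best)
  }
  structure(out, class = "baseline_decoder")
}

#' Predict with a fitted baseline decoder
#'
#' @param object A `baseline_decoder`.
#' @param features A `feature_tensor_series` or design matrix.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.baseline_decoder <- function(object, features, ...) {
  X <- if (inherits(features, "feature_tensor_series"))
    flatten_features(features) else as.matrix(features)
  if (object$method == "pls") {
    pls_predict_raw(object$fit, X)
  } else {
    as.numeric(stats::predict(object$fit, X, s = object$lambda))
  }
}

# train + predict for one fold, dispatching on decoder label
fit_and_predict <- function(decoder, train_fts, y_train, test_fts, config) {
  if (decoder == "cnn") {
    model <- train_cnn(train_fts, y_train, config)
    predict(model, test_fts)
  } else {
    model <- fit_baseline(train_fts, y_train, method = decoder)
    predict(model, test_fts)
  }
}

subset_tensor_time <- function(fts, idx) {
  structure(fts[, , , idx, drop = FALSE], t = attr(fts, "t")[idx],
            class = "feature_tensor_series")
}

#' Cross-validated decoding of all joints
#'
#' Splits the session into `k` contiguous temporal blocks; each block serves
#' once as the test set while the others train the decoder. Feature and
#' target normalization, as well as baseline hyperparameter selection, use
#' training-fold data only.
#'
#' @param prep Output of [preprocess_session()] (tensors + targets +
#'   channel map), or a compatible list.
#' @param decoder `"cnn"`, `"pls"` or `"lasso"`.
#' @param subset Channel subset label (see [subset_channels()]).
#' @param k Number of folds (default 3).
#' @param config A [cnn_config()] used when `decoder = "cnn"`; its `seed`
#'   controls all decoder randomness.
#' @param joints Joint rows to decode (default all).
#' @return A `decode_result` data frame with columns `decoder`, `subset`,
#'   `joint`, `fold`, `r2`.
#' @export
crossvalidate <- function(prep, decoder = c("cnn", "pls", "lasso"),
                          subset = "all", k = 3, config = cnn_config(),
                          joints = NULL) {
  decoder <- match.arg(decoder)
  fts <- subset_channels(prep$tensors, subset, prep$channel_map)
  targets <- prep$targets
  if (is.null(joints)) joints <- seq_len(nrow(targets))
  n <- dim(fts)[4]
  fold <- cv_folds(n, k)
  jn <- rownames(targets)
  if (is.null(jn)) jn <- paste0("joint", seq_len(nrow(targets)))
  rows <- list()
  for (j in joints) {
    for (f in seq_len(k)) {
      tr <- fold != f
      yhat <- fit_and_predict(decoder,
                              subset_tensor_time(fts, which(tr)),
                              targets[j, tr],
                              subset_tensor_time(fts, which(!tr)), config)
      rows[[length(rows) + 1]] <- data.frame(
        decoder = decoder, subset = subset, joint = jn[j], fold = f,
        r2 = r_squared(targets[j, !tr], yhat), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- config$seed
  class(out) <- c("decode_result", class(out))
  out
}

#' Mean R-squared per joint of a decode result
#'
#' @param result A `decode_result`.
#' @return Named vector of fold-averaged R-squared per joint.
#' @export
mean_r2 <- function(result) {
  tapply(result$r2, result$joint, mean)
}
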