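test_that("R^2 scorer matches the direct formula", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 100)
  y <- c(4, 7, 1, 3)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 2)), 50)
  # independent oracle on random series
  oracle <- function(y, yh) 100 * (1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  withr::with_seed(9, {
    for (i in 1:100) {
      n <- sample(10:200, 1)
      y <- rnorm(n)
      yh <- y + rnorm(n, sd = runif(1, 0, 2))
      expect_equal(r_squared(y, yh), oracle(y, yh), tolerance = 1e-10)
    }
  })
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("cross-validation folds are equal contiguous blocks", {
  f <- cv_folds(900, 3)
  expect_equal(as.numeric(table(f)), c(300, 300, 300))
  expect_true(all(diff(f) >= 0))  # contiguous
  f2 <- cv_folds(10, 3)
  expect_equal(as.numeric(table(f2)), c(4, 3, 3))
  expect_error(cv_folds(5, 3), "too few")
})

test_that("channel subsets extract the published electrode groupings", {
  expect_equal(subset_electrodes("lateral"), c(1, 4, 5, 8))
  expect_equal(subset_electrodes("dorsal"), c(2, 3, 6, 7))
  expect_equal(subset_electrodes("left"), c(3, 4, 7, 8))
  expect_equal(subset_electrodes("right"), c(1, 2, 5, 6))
  expect_equal(subset_electrodes("all"), 1:8)
  expect_equal(sort(union(subset_electrodes("left"), subset_electrodes("right"))), 1:8)
  expect_equal(length(intersect(subset_electrodes("left"),
                                subset_electrodes("right"))), 0)
  pp <- quick_prep()
  lat <- subset_channels(pp$tensors, "lateral", pp$channel_map)
  expect_equal(dim(lat)[1], 4)
  expect_equal(attr(lat, "electrodes"), c(1, 4, 5, 8))
  expect_equal(unname(lat[2, , , 10]), unname(pp$tensors[4, , , 10]))
  all_t <- subset_channels(pp$tensors, "all", pp$channel_map)
  expect_equal(dim(all_t), dim(pp$tensors))
  expect_error(subset_channels(pp$tensors, "ventral"), "arg")
})

test_that("a mean-predictor decoder scores ~0 under cross-validation", {
  withr::with_seed(12, {
    n <- 600
    y <- rnorm(n)
    fold <- cv_folds(n, 3)
    r2 <- vapply(1:3, function(f) {
      r_squared(y[fold == f], rep(mean(y[fold != f]), sum(fold == f)))
    }, numeric(1))
    expect_lt(abs(mean(r2)), 5)
  })
})

test_that("Lasso recovers an exactly linear single-feature target", {
  pp <- quick_prep()
  fts <- pp$tensors
  n <- dim(fts)[4]
  y <- 3 * fts[2, 1, 2, ] + 1        # linear in one feature, no noise
  tr <- seq_len(floor(2 * n / 3))
  te <- setdiff(seq_len(n), tr)
  fit <- fit_baseline(lfpdecode:::subset_tensor_time(fts, tr), y[tr], "lasso")
  yh <- predict(fit, lfpdecode:::subset_tensor_time(fts, te))
  expect_gte(r_squared(y[te], yh), 99)
})

test_that("baselines score at or below zero on a pure-noise target", {
  pp <- quick_prep()
  fts <- pp$tensors
  n <- dim(fts)[4]
  withr::with_seed(13, y <- rnorm(n))
  tr <- seq_len(floor(2 * n / 3))
  te <- setdiff(seq_len(n), tr)
  for (m in c("pls", "lasso")) {
    fit <- fit_baseline(lfpdecode:::subset_tensor_time(fts, tr), y[tr], m)
    yh <- predict(fit, lfpdecode:::subset_tensor_time(fts, te))
    expect_lt(r_squared(y[te], yh), 10)
  }
})

test_that("full-rank PLS on a noiseless linear target matches least squares", {
  withr::with_seed(14, {
    n <- 60; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- as.numeric(X %*% beta) + 2
    fit <- lfpdecode:::pls_fit_raw(X, y, ncomp = p)
    ols <- stats::lm.fit(cbind(1, X), y)$coefficients
    expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
    expect_equal(fit$coef, unname(ols[-1]), tolerance = 1e-6)
  })
})

test_that("constant features are rejected", {
  fts <- structure(array(1, dim = c(2, 3, 2, 30)), t = seq(0.1, 3, by = 0.1),
                   class = "feature_tensor_series")
  expect_error(fit_baseline(fts, rnorm(30), "pls"), "constant")
})

test_that("no leakage: training artifacts ignore the test fold entirely", {
  pp <- quick_prep()
  fts <- pp$tensors
  n <- dim(fts)[4]
  fold <- cv_folds(n, 3)
  tr <- which(fold != 3)
  y <- pp$targets[1, ]
  corrupted <- fts
  corrupted[, , , fold == 3] <- 1e6   # vandalize the test fold
  corrupted <- structure(corrupted, t = attr(fts, "t"),
                         class = "feature_tensor_series")
  m1 <- train_cnn(lfpdecode:::subset_tensor_time(fts, tr), y[tr], tiny_cnn())
  m2 <- train_cnn(lfpdecode:::subset_tensor_time(corrupted, tr), y[tr], tiny_cnn())
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$norm, m2$norm)
  b1 <- fit_baseline(lfpdecode:::subset_tensor_time(fts, tr), y[tr], "pls")
  b2 <- fit_baseline(lfpdecode:::subset_tensor_time(corrupted, tr), y[tr], "pls")
  expect_identical(b1$fit$coef, b2$fit$coef)
})

test_that("crossvalidate reports 3 folds per joint and is seed-deterministic", {
  pp <- quick_prep()
  res1 <- crossvalidate(pp, decoder = "pls", joints = c(1, 4))
  expect_equal(nrow(res1), 6)
  expect_equal(sort(unique(res1$fold)), 1:3)
  expect_true(all(res1$r2 <= 100))
  res_cnn_a <- crossvalidate(pp, decoder = "cnn", joints = 1,
                             config = tiny_cnn(seed = 3))
  res_cnn_b <- crossvalidate(pp, decoder = "cnn", joints = 1,
                             config = tiny_cnn(seed = 3))
  expect_identical(res_cnn_a$r2, res_cnn_b$r2)
})
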