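test_that("forward pass matches a brute-force R oracle", {
  withr::with_seed(41, {
    # small geometry exercised exhaustively
    d <- c(4, 5, 3)
    cfg <- cnn_config(n_filters = 3, filter_size = c(3, 4, 2),
                      pool_size = c(2, 2, 2), hidden = 6, seed = 1)
    w <- lfpdecode:::cnn_init_weights(d, cfg)
    for (rep in 1:3) {
      x <- array(rnorm(prod(d)), dim = d)
      ref <- lfpdecode:::cnn_forward_reference(x, w, cfg$filter_size,
                                               cfg$pool_size)
      got <- lfpdecode:::.cnn_predict_cpp(matrix(as.numeric(x), ncol = 1),
                                          as.integer(d), cfg$filter_size,
                                          cfg$pool_size, w)
      expect_equal(got, ref, tolerance = 1e-5)
    }
    # published geometry: 8 x 10 x 7 input, 7 x 6 x 8 filter
    d2 <- c(8, 10, 7)
    cfg2 <- cnn_config(n_filters = 2, hidden = 8, seed = 2)
    w2 <- lfpdecode:::cnn_init_weights(d2, cfg2)
    x2 <- array(rnorm(prod(d2)), dim = d2)
    ref2 <- lfpdecode:::cnn_forward_reference(x2, w2, cfg2$filter_size,
                                              cfg2$pool_size)
    got2 <- lfpdecode:::.cnn_predict_cpp(matrix(as.numeric(x2), ncol = 1),
                                         as.integer(d2), cfg2$filter_size,
                                         cfg2$pool_size, w2)
    expect_equal(got2, ref2, tolerance = 1e-5)
  })
})

test_that("single forward pass yields one finite scalar per tensor", {
  pp <- quick_prep()
  m <- train_cnn(pp$tensors, pp$targets[1, ], tiny_cnn(epochs = 1))
  one <- lfpdecode:::subset_tensor_time(pp$tensors, 1)
  p1 <- predict(m, one)
  expect_length(p1, 1)
  expect_true(is.finite(p1))
  # duplicated input gives identical predictions
  two <- lfpdecode:::subset_tensor_time(pp$tensors, c(5, 5))
  p2 <- predict(m, two)
  expect_identical(p2[1], p2[2])
})

test_that("training on a constant-plus-noise target beats a zero predictor", {
  pp <- quick_prep()
  n <- dim(pp$tensors)[4]
  withr::with_seed(42, y <- 25 + rnorm(n, sd = 0.5))
  m <- train_cnn(pp$tensors, y, tiny_cnn())
  yh <- predict(m, pp$tensors)
  expect_lt(mean((y - yh)^2), mean(y^2))
  # predictions hover near the constant
  expect_lt(abs(mean(yh) - 25), 2)
})

test_that("training loss decreases on a strongly coupled fixture", {
  pp <- strong_prep()
  m <- train_cnn(pp$tensors, pp$targets[1, ], desk_cnn(), track_loss = TRUE)
  expect_length(m$loss, desk_cnn()$epochs + 1)
  expect_lt(m$loss[length(m$loss)], m$loss[1])
})

test_that("identical config and seed give identical models", {
  pp <- quick_prep()
  m1 <- train_cnn(pp$tensors, pp$targets[2, ], tiny_cnn(seed = 17))
  m2 <- train_cnn(pp$tensors, pp$targets[2, ], tiny_cnn(seed = 17))
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, pp$tensors), predict(m2, pp$tensors))
})

test_that("geometry mismatches are rejected", {
  pp <- quick_prep()
  m <- train_cnn(pp$tensors, pp$targets[1, ], tiny_cnn(epochs = 1))
  lat <- subset_channels(pp$tensors, "lateral", pp$channel_map)
  expect_error(predict(m, lat), "geometry")
  expect_error(train_cnn(pp$tensors, pp$targets[1, 1:10], tiny_cnn()),
               "target length")
  expect_error(cnn_config(momentum = 1.2), "momentum")
})

test_that("decoding accuracy is non-decreasing in modulation depth", {
  # parameter-recovery: 90 s sessions at m = 0.2 / 0.5 / 0.8, one joint,
  # final third as test fold, averaged over 3 seeds
  r2_at_m <- function(m, seed) {
    s <- generate_session(synth_config(
      duration = 90, seed = seed, gait = gait_model(cadence = 0.72),
      coupling = coupling_spec(m = matrix(m, 8, 6))))
    pp <- preprocess_session(s)
    n <- dim(pp$tensors)[4]
    fold <- cv_folds(n, 3)
    tr <- which(fold != 3); te <- which(fold == 3)
    mod <- train_cnn(lfpdecode:::subset_tensor_time(pp$tensors, tr),
                     pp$targets[1, tr], desk_cnn(seed = seed))
    r_squared(pp$targets[1, te],
              predict(mod, lfpdecode:::subset_tensor_time(pp$tensors, te)))
  }
  mean_r2 <- vapply(c(0.2, 0.5, 0.8), function(m)
    mean(vapply(1:3, function(s) r2_at_m(m, s), numeric(1))), numeric(1))
  expect_true(all(diff(mean_r2) >= 0))
})
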