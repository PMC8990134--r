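test_that("gait cycles are counted from the ground-truth phase", {
  s <- generate_session(synth_config(duration = 60,
                                     gait = gait_model(cadence = 0.75)))
  cyc <- segment_gait_cycles(s)
  expect_true(abs(n_cycles(cyc) - 45) <= 1)
  expect_true(all(diff(cyc$boundaries) > 0))
  ph <- cyc$phase
  expect_true(all(ph >= 0 & ph < 1))
})

test_that("peak detection recovers cycles from raw kinematics", {
  fs <- 50
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  kin <- matrix(rep(100 + 15 * sin(2 * pi * 0.6 * t), 6), nrow = 6,
                byrow = TRUE)
  s <- as_session(neural = matrix(0, 8, 500 * 30), neural_fs = 500,
                  kinematics = kin, kin_fs = fs)
  cyc <- segment_gait_cycles(s)
  intervals <- diff(cyc$boundaries)
  expect_lt(max(abs(intervals - 1 / 0.6)) / (1 / 0.6), 0.02)
  flat <- as_session(neural = matrix(0, 8, 500 * 30), neural_fs = 500,
                     kinematics = matrix(100, 6, 1500), kin_fs = fs)
  expect_error(segment_gait_cycles(flat), "constant")
})

test_that("cycle averages recover the coupling phase and normalize to zero", {
  cp <- coupling_spec(m = matrix(0, 8, 6))
  cp$m[3, 2] <- 0.8
  cp$psi[3, 2] <- pi / 2    # envelope peaks at 25% of the cycle
  s <- generate_session(synth_config(duration = 90, seed = 51,
                                     gait = gait_model(cadence = 0.72),
                                     coupling = cp))
  f <- extract_features(s)
  tf <- cycle_average(f$env, f$t, segment_gait_cycles(s))
  expect_equal(dim(tf$pct_change), c(8, 6, 100))
  # percent change averages to zero in every channel/band
  expect_lt(max(abs(apply(tf$pct_change, c(1, 2), mean))), 1e-9)
  peak_bin <- which.max(tf$pct_change[3, 2, ])
  expect_lt(min(abs(peak_bin - 25), 100 - abs(peak_bin - 25)), 10)
  # scale invariance of percent change
  tf2 <- cycle_average(f$env * 2, f$t, segment_gait_cycles(s))
  expect_equal(tf2$pct_change, tf$pct_change, tolerance = 1e-9)
  expect_error(cycle_average(f$env, f$t,
                             structure(list(boundaries = c(0, 1), t = 0, fs = 1,
                                            phase = 0), class = "gait_cycle_set")),
               "two complete")
})

test_that("compare_groups: null, strong effect, and Tukey localization", {
  withr::with_seed(61, {
    d_null <- data.frame(value = rnorm(40), g = rep(c("a", "b"), each = 20))
    d_null$value <- ave(d_null$value, d_null$g, FUN = function(v) v - mean(v))
    res <- compare_groups(value ~ g, d_null)
    expect_gt(summary(res$fit)[[1]][["Pr(>F)"]][1], 0.9)
    d_eff <- data.frame(value = c(rnorm(20), rnorm(20, 5)),
                        g = rep(c("a", "b"), each = 20))
    res2 <- compare_groups(value ~ g, d_eff)
    expect_lt(summary(res2$fit)[[1]][["Pr(>F)"]][1], 0.05)
    d3 <- data.frame(value = c(rnorm(20), rnorm(20), rnorm(20, 5)),
                     g = rep(c("a", "b", "c"), each = 20))
    tk <- compare_groups(value ~ g, d3)$tukey$g
    sig <- rownames(tk)[tk[, "p adj"] < 0.05]
    expect_setequal(sig, c("c-a", "c-b"))
  })
  expect_error(compare_groups(value ~ g,
                              data.frame(value = 1:3, g = c("a", "a", "b"))),
               "two observations")
})

test_that("power simulation: N(0,1) vs N(5,1) rejected in >= 99% of runs", {
  withr::with_seed(62, {
    rej <- replicate(200, {
      d <- data.frame(value = c(rnorm(20), rnorm(20, 5)),
                      g = rep(c("a", "b"), each = 20))
      summary(stats::aov(value ~ g, d))[[1]][["Pr(>F)"]][1] < 0.05
    })
    expect_gte(mean(rej), 0.99)
  })
})

test_that("cadence analysis groups sessions and finds the theta effect", {
  mk <- function(cad, seed) generate_session(synth_config(
    duration = 45, seed = seed, gait = gait_model(cadence = cad)))
  sessions <- list(mk(0.60, 1), mk(0.63, 2), mk(0.66, 3),
                   mk(0.74, 4), mk(0.76, 5), mk(0.79, 6))
  res <- cadence_analysis(sessions)
  expect_equal(res$band, band_specs()$name)
  expect_equal(attr(res, "groups"),
               rep(c("lower", "higher"), each = 3))
  # built-in theta/cadence linkage: higher cadence -> larger theta envelope
  th <- res[res$band == "theta", ]
  expect_gt(th$mean_higher, th$mean_lower)
  # a session inside the excluded window is dropped
  sessions2 <- c(sessions, list(mk(0.70, 7)))
  res2 <- cadence_analysis(sessions2)
  expect_equal(length(attr(res2, "groups")), 6)
  expect_error(cadence_analysis(list(mk(0.6, 8))), "each cadence group")
})
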