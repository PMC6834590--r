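test_that("classify_pre_state averages the 10 s before the stimulus", {
  norm <- c(rep(0.5, 20), rep(0.01, 10), rep(0.9, 10))  # fps = 1
  out <- classify_pre_state(norm, stim_time_s = 30, fps = 1)
  expect_equal(out$pre_mean, mean(norm[21:30]))
  expect_equal(out$state, "sleep")
})

test_that("state boundaries are inclusive for low_wake", {
  mk <- function(level) rep(level, 40)
  expect_equal(classify_pre_state(mk(0.08), 20, 1)$state, "low_wake")
  expect_equal(classify_pre_state(mk(0.35), 20, 1)$state, "low_wake")
  expect_equal(classify_pre_state(mk(0.0799), 20, 1)$state, "sleep")
  expect_equal(classify_pre_state(mk(0.3501), 20, 1)$state, "high_wake")
  expect_error(classify_pre_state(mk(0.1), 5, 1), "outside")
})

test_that("post_response excludes the valve artifact", {
  norm <- rep(0, 40)
  norm[11:12] <- 100  # artifact frames: (10, 12] s at fps = 1
  norm[13:20] <- 1    # genuine response
  expect_equal(post_response(norm, stim_time_s = 10, fps = 1), 1)
  expect_equal(post_response(norm, 10, 1, artifact_s = 0),
               mean(norm[11:20]))
  expect_error(post_response(norm, 10, 1, post_window_s = 2, artifact_s = 2),
               "smaller")
  expect_error(post_response(norm, 35, 1), "outside")
})

test_that("stimulus_trials builds a tidy table and drops edge trials", {
  norm <- c(rep(0.01, 60), rep(0.5, 60))  # fps = 1; sleeps then wakes
  tab <- stimulus_trials(norm, c(5, 30, 115), 1, stim_kind = "mech_strong")
  # t = 5 lacks a full pre-window; t = 115 lacks a full post-window
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$stim_time_s, 30)
  expect_equal(tab$pre_state, "sleep")
  expect_equal(tab$stim_kind, "mech_strong")
  expect_equal(tab$post_mean, mean(norm[33:40]))
})

test_that("fraction_awake reports the exact fraction and a stable SD", {
  post <- c(rep(0.5, 30), rep(0.01, 20))
  out <- fraction_awake(post, wake_threshold = 0.06, n_boot = 2000, seed = 1)
  expect_equal(out$fraction, 0.6)
  expect_equal(out$n_trials, 50L)
  expect_equal(out$bootstrap_sd, sqrt(0.6 * 0.4 / 50), tolerance = 0.1)
  out2 <- fraction_awake(post, wake_threshold = 0.06, n_boot = 2000, seed = 1)
  expect_identical(out, out2)
  # degenerate: all awake, SD 0
  expect_equal(fraction_awake(rep(1, 10), n_boot = 100, seed = 1)$bootstrap_sd,
               0)
})

test_that("resampling_test p-values behave at the extremes", {
  same <- resampling_test(rep(c(0, 1), 25), rep(c(0, 1), 25),
                          n_iter = 2000, seed = 2)
  expect_equal(same$diff_obs, 0)
  expect_gt(same$p_raw, 0.5)
  extreme <- resampling_test(rep(1, 30), rep(0, 30), n_iter = 2000, seed = 2)
  expect_equal(extreme$diff_obs, 1)
  expect_equal(extreme$p_raw, 1 / 2001)
  # Bonferroni adjusts and caps at 1
  expect_equal(extreme$p_adjusted, min(1, extreme$p_raw * 1))
  adj <- resampling_test(rep(c(0, 1), 10), rep(c(0, 1), 10),
                         n_iter = 500, n_comparisons = 10, seed = 3)
  expect_lte(adj$p_adjusted, 1)
  expect_error(resampling_test(numeric(), c(0, 1)), "non-empty")
  expect_error(resampling_test(c(1, NA), c(0, 1)), "NA")
})

test_that("resampling_test matches explicit label shuffling in distribution", {
  withr::with_seed(5, {
    a <- rbinom(40, 1, 0.6); b <- rbinom(35, 1, 0.5)
    fast <- resampling_test(a, b, n_iter = 4000, seed = 11)
    pool <- c(a, b)
    d_obs <- mean(a) - mean(b)
    d_star <- replicate(4000, {
      lab <- sample(pool)
      mean(lab[1:40]) - mean(lab[41:75])
    })
    p_slow <- (1 + sum(abs(d_star) >= abs(d_obs) - 1e-12)) / 4001
    expect_equal(fast$p_raw, p_slow, tolerance = 0.1)
  })
})
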