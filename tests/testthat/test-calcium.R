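test_that("delta_f_over_f matches the hand example", {
  out <- delta_f_over_f(c(5, 4, 6), fps = 1, smooth_s = 0)
  expect_equal(out$dFF, c(0, 0, 0.5))
  expect_equal(out$F0, c(5, 4, 4))
})

test_that("dF/F invariants hold and smoothing is applied first", {
  withr::with_seed(3, F <- runif(500, 0.5, 2))
  out <- delta_f_over_f(F, fps = 5, smooth_s = 3)
  expect_true(all(diff(out$F0) <= 0))
  expect_true(all(out$dFF >= 0))
  expect_equal(out$F, wormstate:::moving_average(F, 15L))
  # scale invariance: F -> cF leaves dFF unchanged
  out2 <- delta_f_over_f(10 * F, fps = 5, smooth_s = 3)
  expect_equal(out2$dFF, out$dFF, tolerance = 1e-12)
  expect_error(delta_f_over_f(c(1, 0, 2), smooth_s = 0), "Degenerate")
  expect_error(delta_f_over_f(c(1, 2), fps = NULL, smooth_s = 3), "fps")
})

test_that("extract_neuron_trace is the exact ROI mean", {
  vid <- array(0, c(20, 20, 2))
  vid[7:14, 7:14, 1] <- 10
  vid[7:14, 7:14, 2] <- 20
  expect_equal(extract_neuron_trace(vid, c(10.5, 10.5)), c(10, 20))
  # half the 8x8 ROI covers the block
  expect_equal(extract_neuron_trace(vid, c(10.5, 14.5))[1], 5)
  expect_error(extract_neuron_trace(vid, c(2, 2)), "clipped")
})

test_that("extract_ris_trace averages the top pixels of the soma window", {
  fr <- matrix(0, 50, 50)
  fr[20:24, 20:23] <- 100  # exactly 20 bright pixels
  expect_equal(extract_ris_trace(fr, c(22, 22)), 100)
  fr[20, 20] <- 500
  expect_equal(extract_ris_trace(fr, c(22, 22)), (500 + 19 * 100) / 20)
  expect_warning(v <- extract_ris_trace(fr, c(3, 3)), "clipped")
  expect_true(is.finite(v))
})

test_that("delta_r_over_r is identically zero for identical channels", {
  dff <- c(0.5, 0.3, 1.2, 0.8, 0.6)
  out <- delta_r_over_r(dff, dff)
  expect_equal(attr(out, "R0"), 1)
  expect_equal(out$dRR, rep(0, 5))
})

test_that("R0 is the 20th percentile of the floored ratio", {
  withr::with_seed(4, {
    for (i in 1:20) {
      gd <- runif(200, 0, 2)
      md <- runif(200, 0, 0.5)
      out <- delta_r_over_r(gd, md)
      R <- gd / pmax(md, 0.01)
      expect_equal(out$R, R)
      expect_equal(attr(out, "R0"), oracle_percentile(R, 20))
      expect_equal(out$dRR, (R - attr(out, "R0")) / attr(out, "R0"))
    }
  })
})

test_that("the denominator floor caps ratio blowups", {
  gd <- c(1, 1); md <- c(0, 1)
  out <- delta_r_over_r(gd, md, denom_floor = 0.01)
  expect_equal(out$R, c(100, 1))
  expect_error(delta_r_over_r(c(1, 1), c(0, 0)), "Degenerate")
  expect_error(delta_r_over_r(1:3, 1:2), "aligned")
})

test_that("displacement_behavior computes mean per-pair displacement", {
  pos <- array(0, c(2, 2, 3))
  pos[1, , ] <- rbind(c(0, 3, 3), c(0, 4, 4))  # 5 px then 0
  pos[2, , ] <- rbind(c(0, 0, 0), c(0, 1, 1))  # 1 px then 0
  out <- displacement_behavior(pos, fps = 1, smoothing_window_s = 0)
  expect_equal(out$raw, c(3, 0))
  pos[2, , 2] <- NA
  expect_warning(out2 <- displacement_behavior(pos, fps = 1,
                                               smoothing_window_s = 0),
                 "Missing")
  expect_equal(out2$raw[1], 5)  # only the intact neuron contributes
})

test_that("state_fluorescence_summary splits by bout membership", {
  bouts <- detect_bouts(rep(c(1, 0, 1), c(10, 10, 10)), 1, 0.5, min_bout_s = 5)
  x <- rep(c(1, 3, 1), c(10, 10, 10))
  sm <- state_fluorescence_summary(x, bouts, fps = 1)
  expect_equal(sm$wake_mean, 1)
  expect_equal(sm$sleep_mean, 3)
  expect_equal(sm$n_sleep, 10L)
})

test_that("RIS-like traces rise during sleep; ordinary neurons fall", {
  sched <- uniform_schedule(3600, seed = 6)
  sim <- simulate_fluorescence(sched, n_neurons = 2, fps = 5,
                               ris_like = TRUE, noise_sd = 0.01, seed = 6)
  bouts <- detect_bouts(
    as.numeric(!schedule_state(sched, 5)$asleep), 5, 0.5)
  ris <- delta_f_over_f(sim$traces$F[sim$traces$channel == "neuron1"], 5)
  ord <- delta_f_over_f(sim$traces$F[sim$traces$channel == "neuron2"], 5)
  sm_ris <- state_fluorescence_summary(ris, bouts, 5)
  sm_ord <- state_fluorescence_summary(ord, bouts, 5)
  expect_gt(sm_ris$sleep_mean, sm_ris$wake_mean)
  expect_lt(sm_ord$sleep_mean, sm_ord$wake_mean)
})

test_that("windowed_correlation finds per-window r and shuffles pairings", {
  n <- 40
  x <- sin(seq_len(n)); y <- -x
  out <- windowed_correlation(x, y, fps = 1, window_s = 10, n_shuffles = 50,
                              seed = 1)
  expect_equal(nrow(out$window_r), 4L)
  expect_equal(out$window_r$r, rep(-1, 4), tolerance = 1e-12)
  expect_equal(nrow(out$shuffled), 200L)
  expect_error(windowed_correlation(x[1:10], y[1:10], 1, window_s = 10),
               "at least 2")
  expect_error(windowed_correlation(x, y[1:10], 1), "aligned")
})

test_that("constant windows are skipped with a warning", {
  x <- c(rep(1, 10), sin(1:10))
  y <- c(sin(1:10), sin(1:10))
  expect_warning(out <- windowed_correlation(x, y, 1, window_s = 10,
                                             n_shuffles = 10, seed = 1),
                 "Constant")
  expect_equal(out$window_r$window, 2L)
})
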