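test_that("geometry thresholds match the reported configuration table", {
  expect_equal(geometry_threshold("wormotel"), 0.15)
  expect_equal(geometry_threshold("chamber_500um"), 0.15)
  expect_equal(geometry_threshold("chamber_110um"), 0.08)
  expect_equal(geometry_threshold("chamber_50um"), 0.06)
  expect_equal(geometry_threshold("ris_50um"), 0.2)
  expect_error(geometry_threshold("agar_pad"), "Unknown geometry")
})

test_that("a simple quiescent run becomes one half-open bout", {
  act <- rep(c(1, 0, 1), c(90, 135, 90))  # frames 91..225 below threshold
  b <- detect_bouts(act, fps = 3, threshold = 0.15)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_s, 30)
  expect_equal(b$end_s, 75)
})

test_that("the quiescence threshold is strict", {
  act <- rep(c(1, 0.15, 1), c(30, 120, 30))  # exactly at threshold
  expect_equal(nrow(detect_bouts(act, fps = 3, threshold = 0.15)), 0L)
  act2 <- rep(c(1, 0.1499, 1), c(30, 120, 30))
  expect_equal(nrow(detect_bouts(act2, fps = 3, threshold = 0.15)), 1L)
})

test_that("gaps strictly shorter than max_twitch_s merge; 15 s does not", {
  fps <- 3
  mk <- function(gap_frames) {
    rep(c(1, 0, 1, 0, 1), c(30, 90, gap_frames, 90, 30))
  }
  merged <- detect_bouts(mk(44), fps, 0.15)   # 44/3 = 14.67 s gap
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$end_s - merged$start_s, (90 + 44 + 90) / 3)
  split <- detect_bouts(mk(45), fps, 0.15)    # exactly 15 s gap
  expect_equal(nrow(split), 2L)
})

test_that("merging happens before the minimum-bout filter", {
  # two 20-s sub-runs, individually < 30 s, joined by a 10-s twitch gap
  act <- rep(c(1, 0, 1, 0, 1), c(30, 60, 30, 60, 30))
  b <- detect_bouts(act, fps = 3, threshold = 0.15)
  expect_equal(nrow(b), 1L)
  expect_equal(b$end_s - b$start_s, 50)
})

test_that("runs shorter than min_bout_s are discarded", {
  act <- rep(c(1, 0, 1), c(30, 89, 30))  # 29.67 s
  expect_equal(nrow(detect_bouts(act, fps = 3, threshold = 0.15)), 0L)
  act2 <- rep(c(1, 0, 1), c(30, 90, 30))  # exactly 30 s: kept
  expect_equal(nrow(detect_bouts(act2, fps = 3, threshold = 0.15)), 1L)
})

test_that("a bout truncated by the recording end is kept if long enough", {
  act <- rep(c(1, 0), c(60, 120))  # quiescent to the end
  b <- detect_bouts(act, fps = 3, threshold = 0.15)
  expect_equal(nrow(b), 1L)
  expect_equal(b$end_s, 60)  # = recording length
})

test_that("detect_bouts handles empty and all-quiescent traces", {
  b0 <- detect_bouts(numeric(), fps = 3, threshold = 0.15)
  expect_equal(nrow(b0), 0L)
  b1 <- detect_bouts(rep(0, 300), fps = 3, threshold = 0.15)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$start_s, 0)
  expect_error(detect_bouts(c(0, NA), fps = 3, threshold = 0.15), "NA")
})

test_that("tidy and glance expose the standard summaries", {
  act <- rep(c(1, 0, 1, 0, 1), c(300, 180, 720, 270, 9330))
  b <- detect_bouts(act, fps = 3, threshold = 0.15, animal_id = "w1")
  td <- tidy(b)
  expect_equal(td$start_s, c(100, 400))
  expect_equal(td$end_s, c(160, 490))
  expect_equal(td$duration_s, c(60, 90))
  expect_equal(td$animal_id, c("w1", "w1"))
  gl <- glance(b)
  expect_equal(gl$n_bouts, 2L)
  expect_equal(gl$total_sleep_s, 150)
  expect_equal(gl$onset_s, 100)
  expect_equal(gl$sleep_fraction, 150 / 3600)
})

test_that("bout_statistics wake bouts and homeostasis pairs by hand", {
  # recording 3600 s, bouts [100,160) and [400,490)
  act <- rep(c(1, 0, 1, 0, 1), c(300, 180, 720, 270, 9330))
  st <- bout_statistics(detect_bouts(act, fps = 3, threshold = 0.15))
  expect_equal(st$sleep_bout_lengths_s[[1]], c(60, 90))
  # wake bouts: inter-bout gap + terminal gap; pre-first wake excluded
  expect_equal(st$wake_bout_lengths_s[[1]], c(240, 3110))
  pairs <- st$homeostasis_pairs[[1]]
  expect_equal(pairs$preceding_wake_s, 240)
  expect_equal(pairs$sleep_bout_s, 90)
})

test_that("bout_statistics of an empty bout set is all-empty", {
  st <- bout_statistics(detect_bouts(rep(1, 300), fps = 3, threshold = 0.15))
  expect_equal(st$n_bouts, 0L)
  expect_equal(st$total_sleep_s, 0)
  expect_true(is.na(st$onset_s))
  expect_length(st$wake_bout_lengths_s[[1]], 0L)
  expect_equal(nrow(st$homeostasis_pairs[[1]]), 0L)
})

test_that("detect_bouts matches the brute-force oracle on structured traces", {
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(100:2000, 1)
      act <- rbinom(n, 1, runif(1, 0.1, 0.9))
      fps <- sample(c(1, 2, 3), 1)
      mb <- runif(1, 0, 40)
      mt <- runif(1, 0, 20)
      got <- detect_bouts(act, fps, 0.5, mb, mt)
      want <- oracle_bouts(act, fps, 0.5, mb, mt)
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
    }
  })
})

test_that("bout_sensitivity total sleep is non-increasing in min_bout_s", {
  sched <- sample_bout_schedule(7200, seed = 3)
  tr <- schedule_activity_trace(sched, seed = 3)
  norm <- normalize_activity(tr$raw, fps = 3)
  sens <- bout_sensitivity(norm, 3, 0.15, min_bout_grid = c(15, 30, 60))
  expect_equal(sens$min_bout_s, c(15, 30, 60))
  expect_true(all(diff(sens$total_sleep_s) <= 0))
  expect_true(all(diff(sens$n_bouts) <= 0))
})
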