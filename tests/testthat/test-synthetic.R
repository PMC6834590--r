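test_that("bout_schedule validates its inputs", {
  expect_s3_class(
    bout_schedule(data.frame(start_s = 60, end_s = 180), duration_s = 600),
    "bout_schedule"
  )
  expect_error(
    bout_schedule(data.frame(start_s = 10, end_s = 10), duration_s = 100),
    "end_s > start_s"
  )
  expect_error(
    bout_schedule(data.frame(start_s = c(0, 50), end_s = c(60, 90)),
                  duration_s = 100),
    "non-overlapping"
  )
  expect_error(
    bout_schedule(data.frame(start_s = 0, end_s = 200), duration_s = 100),
    "contained"
  )
  expect_error(
    bout_schedule(data.frame(start_s = 10, end_s = 60),
                  twitches = data.frame(time_s = 70, duration_s = 2),
                  duration_s = 100),
    "inside a sleep interval"
  )
  expect_error(
    bout_schedule(data.frame(start_s = 10, end_s = 60),
                  twitches = data.frame(time_s = 20, duration_s = 15),
                  duration_s = 100),
    "less than 15"
  )
})

test_that("sample_bout_schedule satisfies its own invariants", {
  for (s in 1:5) {
    sched <- sample_bout_schedule(7200, seed = s)
    iv <- sched$intervals
    expect_true(all(iv$end_s > iv$start_s))
    expect_true(all(iv$start_s >= 0 & iv$end_s <= 7200))
    if (nrow(iv) > 1L) {
      expect_true(all(iv$start_s[-1] >= iv$end_s[-nrow(iv)]))
    }
    # truncated-exponential durations: every non-truncated bout >= 30 s
    full <- iv$end_s < 7200
    expect_true(all((iv$end_s - iv$start_s)[full] >= 30))
    tw <- sched$twitches
    if (nrow(tw) > 0L) {
      expect_true(all(tw$duration_s >= 1 & tw$duration_s < 15))
      inside <- vapply(seq_len(nrow(tw)), function(i) {
        any(iv$start_s <= tw$time_s[i] &
              tw$time_s[i] + tw$duration_s[i] <= iv$end_s)
      }, logical(1))
      expect_true(all(inside))
    }
  }
  expect_identical(sample_bout_schedule(3600, seed = 9)$intervals,
                   sample_bout_schedule(3600, seed = 9)$intervals)
})

test_that("schedule_state rasterizes half-open intervals at frame resolution", {
  sched <- bout_schedule(data.frame(start_s = 2, end_s = 4), duration_s = 6)
  st <- schedule_state(sched, fps = 2)
  expect_equal(nrow(st), 12L)
  expect_equal(st$asleep, rep(c(FALSE, TRUE, FALSE), c(4, 4, 4)))
})

test_that("schedule_activity_trace has frame-pair length and state levels", {
  sched <- bout_schedule(data.frame(start_s = 100, end_s = 300),
                         duration_s = 600)
  tr <- schedule_activity_trace(sched, fps = 3, seed = 1)
  expect_equal(nrow(tr), 600 * 3 - 1)
  expect_true(all(tr$raw >= 0))
  asleep <- tr$time_s >= 100 & tr$time_s < 300
  expect_gt(mean(tr$raw[!asleep]), 250)
  expect_lt(mean(tr$raw[asleep]), 10)
  expect_identical(tr, schedule_activity_trace(sched, fps = 3, seed = 1))
})

test_that("twitch frames sit between sleep and wake levels", {
  sched <- bout_schedule(
    data.frame(start_s = 0, end_s = 600),
    twitches = data.frame(time_s = 300, duration_s = 10),
    duration_s = 600
  )
  tr <- schedule_activity_trace(sched, fps = 3, seed = 2)
  tw <- tr$time_s >= 300 & tr$time_s < 310
  expect_gt(mean(tr$raw[tw]), 80)
  expect_lt(mean(tr$raw[tw]), 150)  # 0.35 * 300 = 105
})

test_that("render_worm_video returns the right shape with full truth", {
  sched <- bout_schedule(data.frame(start_s = 20, end_s = 60),
                         duration_s = 90)
  cfg <- worm_video_config(fps = 1, seed = 4)
  out <- render_worm_video(cfg, sched)
  expect_equal(dim(out$video), c(64L, 128L, 90L))
  expect_true(is.integer(out$video))
  expect_true(all(out$video >= 0L & out$video <= 255L))
  expect_length(out$truth$centerlines, 90L)
  expect_equal(out$truth$asleep, schedule_state(sched, 1)$asleep)
  # frozen sleep posture: identical centerlines while asleep, no twitch
  sl <- which(out$truth$asleep & !out$truth$twitching)
  expect_equal(out$truth$centerlines[[sl[1]]],
               out$truth$centerlines[[sl[length(sl)]]])
  # sleep arc curvature is the configured multiple of mean wake curvature
  arc <- out$truth$centerlines[[sl[1]]]
  expect_equal(dimensionless_curvature(arc),
               1.15 * out$truth$wake_mean_curvature, tolerance = 0.01)
  out2 <- render_worm_video(cfg, sched)
  expect_identical(out$video, out2$video)
})

test_that("simulate_fluorescence has state contrast, RIS inversion, bleaching", {
  sched <- bout_schedule(data.frame(start_s = 100, end_s = 300),
                         duration_s = 600)
  sim <- simulate_fluorescence(sched, n_neurons = 3, fps = 5,
                               ris_like = TRUE, noise_sd = 0, seed = 1)
  tr <- sim$traces
  n2 <- tr[tr$channel == "neuron2", ]
  n1 <- tr[tr$channel == "neuron1", ]
  red <- tr[tr$channel == "red", ]
  asleep <- sim$truth$asleep[sim$truth$channel == "neuron1"]
  expect_equal(mean(n2$F[asleep]) / mean(n2$F[!asleep]), 0.4)
  expect_equal(mean(n1$F[asleep]) / mean(n1$F[!asleep]), 2)
  expect_true(all(red$F == 1))  # state-independent reference
  bl <- simulate_fluorescence(sched, n_neurons = 1, fps = 5,
                              bleach_tau_s = 300, noise_sd = 0)$traces
  redb <- bl$F[bl$channel == "red"]
  expect_equal(redb, exp(-(seq_along(redb) - 1) / 5 / 300))
})

test_that("render_puncta_image gives exact areas and excludes distractors", {
  out <- render_puncta_image(c(128, 128), n_puncta = 8,
                             distractor_areas = c(1, 40), seed = 2)
  expect_equal(nrow(out$truth), 8L)
  expect_true(all(out$truth$area_px >= 2 & out$truth$area_px <= 30))
  # rendered puncta pixels = truth areas + distractor areas
  expect_equal(sum(out$image == 200), sum(out$truth$area_px) + 1 + 40)
  expect_true(all(out$background == 10))
  expect_identical(
    out$image,
    render_puncta_image(c(128, 128), n_puncta = 8,
                        distractor_areas = c(1, 40), seed = 2)$image
  )
})
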