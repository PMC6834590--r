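test_that("circumcurvature is exact on known circles", {
  expect_equal(circumcurvature(c(0, 0), c(1, 1), c(2, 0)), 1)  # R = 1
  th <- c(0.2, 1.1, 2.5)
  pts <- cbind(5 * cos(th), 5 * sin(th))
  expect_equal(circumcurvature(pts[1, ], pts[2, ], pts[3, ]), 1 / 5)
  expect_equal(circumcurvature(c(0, 0), c(1, 0), c(2, 0)), 0)  # collinear
  expect_error(circumcurvature(c(0, 0), c(0, 0), c(1, 1)), "distinct")
})

test_that("a 20-point centerline yields 18 local curvatures", {
  th <- seq(0, 1, length.out = 20)
  arc <- cbind(10 * sin(th), 10 * (1 - cos(th)))
  expect_length(centerline_curvatures(arc), 18L)
  expect_equal(centerline_curvatures(arc), rep(1 / 10, 18), tolerance = 1e-9)
})

test_that("resample_centerline spaces points equally in arclength", {
  pts <- cbind(c(0, 0, 0, 0), c(0, 1, 5, 10))  # uneven straight polyline
  rs <- resample_centerline(pts, 6L)
  expect_equal(rs[, 2], seq(0, 10, length.out = 6))
  expect_equal(rs[, 1], rep(0, 6))
  # duplicated points (zero-length segments) are tolerated
  rs2 <- resample_centerline(rbind(pts[1, ], pts), 6L)
  expect_equal(rs2, rs)
})

test_that("dimensionless curvature is L/R on arcs and ~0 when straight", {
  for (R in c(10, 20, 30, 40, 50)) {
    L <- 0.8 * R * pi  # keep span below a full circle
    th <- seq(0, L / R, length.out = 100)
    arc <- cbind(R * sin(th), R * (1 - cos(th)))
    expect_equal(dimensionless_curvature(arc), L / R, tolerance = 0.02)
  }
  line <- cbind(seq(0, 60, length.out = 50), rep(3, 50))
  expect_lt(dimensionless_curvature(line), 0.05)
})

test_that("dimensionless curvature is rotation invariant", {
  th <- seq(0, 2, length.out = 80)
  arc <- cbind(15 * sin(th), 15 * (1 - cos(th)))
  rot <- arc %*% matrix(c(0, -1, 1, 0), 2, 2)  # 90 degrees
  expect_equal(dimensionless_curvature(rot), dimensionless_curvature(arc),
               tolerance = 1e-9)
})

test_that("extract_centerline recovers a rendered worm", {
  cl_true <- wormstate:::arc_centerline(60, 40)
  cl_true <- sweep(cl_true, 2, c(32, 64), "+")
  img <- wormstate:::rasterize_worm(cl_true, c(64, 128), 5)
  pf <- extract_centerline(img)
  expect_true(pf$valid)
  expect_equal(nrow(pf$centerline), 20L)
  expect_equal(pf$body_length_px, 60, tolerance = 0.1)
  expect_equal(dimensionless_curvature(pf), 60 / 40, tolerance = 0.1)
})

test_that("blank frames and sub-minimum objects are invalid", {
  expect_false(extract_centerline(matrix(0, 32, 32))$valid)
  tiny <- matrix(0, 32, 32); tiny[10:11, 10:12] <- 255
  expect_false(extract_centerline(tiny, min_object_px = 30)$valid)
})

test_that("background subtraction isolates the animal", {
  bg <- matrix(40, 64, 128)
  cl <- sweep(wormstate:::arc_centerline(60, 60), 2, c(32, 64), "+")
  img <- wormstate:::rasterize_worm(cl, c(64, 128), 5) + bg
  pf <- extract_centerline(img, background = bg)
  expect_true(pf$valid)
  expect_equal(pf$body_length_px, 60, tolerance = 0.1)
  expect_error(extract_centerline(img, background = matrix(40, 10, 10)),
               "same shape")
})

test_that("video_posture applies the 80% body-length gate", {
  mk <- function(len) {
    cl <- sweep(wormstate:::arc_centerline(len, 100), 2, c(32, 64), "+")
    wormstate:::rasterize_worm(cl, c(64, 128), 5)
  }
  vid <- array(0, c(64, 128, 4))
  vid[, , 1] <- mk(60); vid[, , 2] <- mk(60)
  vid[, , 3] <- mk(40)  # foreshortened: below 80% of the mean length
  vid[, , 4] <- mk(60)
  post <- video_posture(vid, fps = 1)
  expect_equal(post$valid, c(TRUE, TRUE, FALSE, TRUE))
  post_run <- video_posture(vid, fps = 1, length_rule = "running")
  expect_equal(post_run$valid, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("curvature_by_state separates wake and sleep postures", {
  sched <- bout_schedule(data.frame(start_s = 30, end_s = 90),
                         duration_s = 120)
  out <- render_worm_video(worm_video_config(seed = 5), sched)
  post <- video_posture(out$video, fps = 3)
  bouts <- detect_bouts(as.numeric(!out$truth$asleep), 3, 0.5)
  cbs <- curvature_by_state(post, bouts, fps = 3)
  expect_gt(cbs$sleep_mean, cbs$wake_mean)
  expect_equal(cbs$sleep_mean / cbs$wake_mean, 1.15, tolerance = 0.05)
  expect_equal(cbs$wake_mean, out$truth$wake_mean_curvature,
               tolerance = 0.05)
})
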