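# Worm centerline extraction and dimensionless body curvature.

#' Curvature of the circle through three points
#'
#' Fits the circumscribed circle of the triangle `p1 p2 p3` and returns
#' `1 / R`, where `R = abc / 4K` (side lengths `a, b, c`, triangle area
#' `K`). Near-collinear points (area below `area_tol`) return curvature 0.
#'
#' @param p1,p2,p3 Numeric length-2 points `(row, col)` in pixels.
#' @param area_tol Triangle-area tolerance below which the points are
#'   treated as collinear (default `1e-9` px^2).
#' @return Curvature in 1/pixels.
#' @export
#' @examples
#' circumcurvature(c(0, 0), c(1, 1), c(2, 0))  # circumradius 1
circumcurvature <- function(p1, p2, p3, area_tol = 1e-9) {
  pts <- rbind(p1, p2, p3)
  if (anyDuplicated(pts)) abort("Points must be distinct.")
  a <- sqrt(sum((p2 - p3)^2))
  b <- sqrt(sum((p1 - p3)^2))
  c_ <- sqrt(sum((p1 - p2)^2))
  cross <- (p2[1L] - p1[1L]) * (p3[2L] - p1[2L]) -
    (p2[2L] - p1[2L]) * (p3[1L] - p1[1L])
  K <- abs(cross) / 2
  if (K < area_tol) return(0)
  4 * K / (a * b * c_)
}

#' Local curvatures along a centerline
#'
#' Circle-fit curvature for every three adjacent points: a 20-point
#' centerline yields 18 values.
#'
#' @param centerline Numeric matrix `n x 2` of ordered `(row, col)` points.
#' @inheritParams circumcurvature
#' @return Numeric vector of length `n - 2` (1/pixels).
#' @export
centerline_curvatures <- function(centerline, area_tol = 1e-9) {
  n <- nrow(centerline)
  if (n < 3L) abort("Need at least 3 centerline points.")
  vapply(seq_len(n - 2L), function(i) {
    circumcurvature(centerline[i, ], centerline[i + 1L, ],
                    centerline[i + 2L, ], area_tol)
  }, numeric(1L))
}

#' Arclength of a polyline
#' @noRd
polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Resample a polyline to points equally spaced in arclength
#'
#' @param pts Numeric matrix `m x 2` of ordered points.
#' @param n Number of output points (default 20).
#' @return An `n x 2` matrix spanning the same curve.
#' @export
resample_centerline <- function(pts, n = 20L) {
  if (nrow(pts) < 2L) abort("Need at least 2 points to resample.")
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 0)  # drop zero-length segments for interpolation
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  target <- seq(0, s[length(s)], length.out = n)
  cbind(
    stats::approx(s, pts[, 1L], xout = target)$y,
    stats::approx(s, pts[, 2L], xout = target)$y
  )
}

#' Dimensionless mean body curvature
#'
#' Mean of the local circle-fit curvatures multiplied by the body length
#' (1/px x px), yielding a dimensionless posture measure: 0 for a straight
#' worm, `L / R` for a circular arc of arclength `L` and radius `R`.
#'
#' @param x A `posture_frame` from [extract_centerline()], or a numeric
#'   matrix of ordered centerline points (resampled to `n_points` first).
#' @param n_points Number of equally spaced points used when `x` is a raw
#'   point matrix (default 20).
#' @return Dimensionless curvature, or `NA` for an invalid frame.
#' @export
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' arc <- cbind(10 * sin(th), 10 * cos(th))  # half circle, R = 10
#' dimensionless_curvature(arc)              # ~ pi
dimensionless_curvature <- function(x, n_points = 20L) {
  if (inherits(x, "posture_frame")) {
    if (!isTRUE(x$valid)) return(NA_real_)
    cl <- x$centerline
    len <- x$body_length_px
  } else {
    cl <- resample_centerline(as.matrix(x), n_points)
    len <- polyline_length(cl)
  }
  mean(centerline_curvatures(cl)) * len
}

# ---- image-based extraction ----------------------------------------------

#' Otsu threshold from a 256-bin histogram
#' @noRd
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = 257L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), 256L)
  w <- cumsum(h)
  mids <- (breaks[-1L] + breaks[-257L]) / 2
  mu <- cumsum(h * mids)
  tot <- w[256L]; mu_t <- mu[256L]
  between <- (mu_t * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Zhang-Suen morphological thinning
#'
#' Iteratively peels a binary mask down to a 1-pixel-wide skeleton.
#' @param mask Logical matrix.
#' @return Logical matrix skeleton.
#' @noRd
zhang_suen_thin <- function(mask) {
  img <- mask * 1L
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north: p2..p9
      p2 <- shift(img, -1L, 0L); p3 <- shift(img, -1L, 1L)
      p4 <- shift(img, 0L, 1L);  p5 <- shift(img, 1L, 1L)
      p6 <- shift(img, 1L, 0L);  p7 <- shift(img, 1L, -1L)
      p8 <- shift(img, 0L, -1L); p9 <- shift(img, -1L, -1L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (pass == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- img == 1L & bsum >= 2L & bsum <= 6L & a == 1L & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

#' Longest geodesic path through a skeleton
#'
#' Treats skeleton pixels as an 8-connected graph with Euclidean edge
#' weights and returns the maximal shortest path between skeleton endpoints
#' (double-sweep; exact on tree-like skeletons, which is what thinning of a
#' worm body produces). Side branches ("spurious pixels") are dropped
#' implicitly because they never lie on the maximal geodesic.
#' @param skel Logical matrix.
#' @return Matrix of ordered `(row, col)` path coordinates.
#' @noRd
skeleton_longest_path <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 2L) return(NULL)
  nr <- nrow(skel)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  lookup <- integer(length(skel))
  lookup[idx] <- seq_along(idx)
  edges <- integer(); weights <- numeric()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[nb] > 0L
    from <- seq_along(idx)[ok][hit]
    to <- lookup[nb][hit]
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, rep(sqrt(sum(off^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges)
    igraph::E(g)$weight <- weights
  }
  # double sweep: farthest vertex from an arbitrary start, then farthest
  # from that; prefer true endpoints (degree <= 1) as the seed
  deg <- igraph::degree(g)
  seed <- if (any(deg <= 1L)) which(deg <= 1L)[1L] else 1L
  d1 <- igraph::distances(g, v = seed)[1L, ]
  d1[!is.finite(d1)] <- -1
  v1 <- which.max(d1)
  d2 <- igraph::distances(g, v = v1)[1L, ]
  d2[!is.finite(d2)] <- -1
  v2 <- which.max(d2)
  path <- igraph::shortest_paths(g, from = v1, to = v2)$vpath[[1L]]
  pv <- as.integer(path)
  cbind(rr[pv], cc[pv])
}

#' Extract a worm centerline from one video frame
#'
#' Background subtraction, contrast stretching, Otsu binarization, removal
#' of all but the largest object, Gaussian smoothing of the mask,
#' morphological thinning, and extraction of the longest skeleton path,
#' resampled to `n_points` points equally spaced in arclength. Body length
#' is the arclength of that path.
#'
#' @param frame Numeric/integer matrix (grayscale frame).
#' @param background Matrix of the empty chamber, same shape (or `NULL`).
#' @param n_points Number of centerline points (default 20).
#' @param min_object_px Smallest foreground object kept (default 30 px).
#' @param smooth_sigma Gaussian sigma (px) for mask smoothing (default 1).
#' @return An object of class `posture_frame`: list with `centerline`
#'   (`n_points x 2`), `body_length_px`, `valid`. Frames with no usable
#'   foreground object return `valid = FALSE`.
#' @export
extract_centerline <- function(frame, background = NULL, n_points = 20L,
                               min_object_px = 30L, smooth_sigma = 1) {
  if (!is.null(background)) {
    if (!all(dim(frame) == dim(background))) {
      abort("`frame` and `background` must have the same shape.")
    }
    frame <- pmax(frame - background, 0)
  }
  frame <- frame * 1.0
  invalid <- structure(
    list(centerline = NULL, body_length_px = NA_real_, valid = FALSE),
    class = "posture_frame"
  )
  if (max(frame) <= 0) return(invalid)
  frame <- frame / max(frame)  # contrast stretch
  mask <- frame > otsu_threshold(frame)
  lab <- label_components_8(mask)
  if (max(lab) == 0L) return(invalid)
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_object_px) return(invalid)
  mask <- lab == which.max(sizes)
  if (smooth_sigma > 0) {
    mask <- gaussian_blur(mask * 1.0, smooth_sigma) > 0.5
  }
  skel <- zhang_suen_thin(mask)
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 3L) return(invalid)
  # The thinned path carries lattice stair-stepping whose wavelength grows
  # unbounded where the body runs nearly parallel to a pixel axis, so no
  # fixed-width filter can remove it without destroying genuine curvature.
  # Instead fit a low-degree polynomial to row(s) and col(s) along the
  # arclength (global least squares, so no boundary constraint biases the
  # end curvatures): degree 8 resolves bends down to about a quarter body
  # length, ample for crawling postures, while rejecting the pixel-scale
  # aliasing of shallow curves.
  if (nrow(path) >= 14L) {
    s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
    deg <- min(8L, nrow(path) - 6L)
    basis <- stats::poly(s, degree = deg)
    path <- cbind(
      stats::lm.fit(cbind(1, basis), path[, 1L])$fitted.values,
      stats::lm.fit(cbind(1, basis), path[, 2L])$fitted.values
    )
  }
  centerline <- resample_centerline(path, n_points)
  structure(
    list(
      centerline = centerline,
      body_length_px = polyline_length(path),
      valid = TRUE
    ),
    class = "posture_frame"
  )
}

#' @export
print.posture_frame <- function(x, ...) {
  if (isTRUE(x$valid)) {
    cat(sprintf("<posture_frame> %d points, body length %.1f px\n",
                nrow(x$centerline), x$body_length_px))
  } else {
    cat("<posture_frame> invalid (no usable foreground object)\n")
  }
  invisible(x)
}

#' Posture analysis of a whole video
#'
#' Runs [extract_centerline()] on every frame and applies the body-length
#' quality gate: frames whose body length falls below 80% of the average
#' length are marked invalid (self-coiled postures foreshorten the
#' skeleton). The reference average is either the whole-video mean (default)
#' or a running mean over frames processed so far.
#'
#' @param video Array `[height, width, frames]`.
#' @param background Background matrix or `NULL`.
#' @param fps Frames per second (for the `time_s` column).
#' @param length_rule `"whole"` (whole-video mean length) or `"running"`.
#' @param min_length_frac Quality gate as a fraction of the average length
#'   (default 0.8).
#' @inheritParams extract_centerline
#' @return A tibble with columns `frame` (0-based), `time_s`,
#'   `body_length_px`, `dimensionless_curvature`, `valid`.
#' @export
video_posture <- function(video, background = NULL, fps = 3,
                          n_points = 20L, length_rule = c("whole", "running"),
                          min_length_frac = 0.8, min_object_px = 30L,
                          smooth_sigma = 1) {
  length_rule <- match.arg(length_rule)
  nf <- dim(video)[3L]
  frames <- purrr::map(seq_len(nf), function(i) {
    extract_centerline(video[, , i], background, n_points,
                       min_object_px, smooth_sigma)
  })
  lens <- purrr::map_dbl(frames, "body_length_px")
  curv <- purrr::map_dbl(frames, dimensionless_curvature)
  valid <- purrr::map_lgl(frames, "valid")
  ref <- if (length_rule == "whole") {
    rep(mean(lens[valid]), nf)
  } else {
    cummean_na(ifelse(valid, lens, NA_real_))
  }
  valid <- valid & !is.na(lens) & lens >= min_length_frac * ref
  tibble(
    frame = seq_len(nf) - 1L,
    time_s = (seq_len(nf) - 1L) / fps,
    body_length_px = lens,
    dimensionless_curvature = curv,
    valid = valid
  )
}

#' Running mean ignoring NA
#' @noRd
cummean_na <- function(x) {
  v <- !is.na(x)
  s <- cumsum(ifelse(v, x, 0))
  n <- cumsum(v)
  out <- s / n
  out[n == 0L] <- NA_real_
  out
}

#' Moving average that skips NA values
#' @noRd
moving_average_na <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  left <- (as.integer(window) - 1L) %/% 2L
  right <- as.integer(window) - 1L - left
  v <- !is.na(x)
  cs <- cumsum(c(0, ifelse(v, x, 0)))
  cn <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L); hi <- pmin(i + right, n)
  sums <- cs[hi + 1L] - cs[lo]
  cnts <- cn[hi + 1L] - cn[lo]
  out <- sums / cnts
  out[cnts == 0L] <- NA_real_
  out
}

#' Mean body curvature during wake and sleep
#'
#' Smooths the per-frame dimensionless curvature over `smooth_s` seconds
#' (skipping invalid frames) and averages it separately over frames inside
#' and outside the detected sleep bouts.
#'
#' @param posture A tibble from [video_posture()] (columns `time_s`,
#'   `dimensionless_curvature`, `valid`).
#' @param bouts A `bout_set` from [detect_bouts()].
#' @param fps Frames per second of the posture series.
#' @param smooth_s Curvature smoothing window in seconds (default 20).
#' @return A one-row tibble with `wake_mean`, `sleep_mean`, `n_wake`,
#'   `n_sleep` (frame counts); a state with no valid frames yields `NA`.
#' @export
curvature_by_state <- function(posture, bouts, fps, smooth_s = 20) {
  x <- posture$dimensionless_curvature
  x[!posture$valid] <- NA_real_
  sm <- moving_average_na(x, window_frames(smooth_s, fps))
  asleep <- rep(FALSE, nrow(posture))
  for (i in seq_len(nrow(bouts))) {
    asleep <- asleep |
      (posture$time_s >= bouts$start_s[i] & posture$time_s < bouts$end_s[i])
  }
  ok <- posture$valid & !is.na(sm)
  wake <- sm[ok & !asleep]
  sleep <- sm[ok & asleep]
  tibble(
    wake_mean = if (length(wake)) mean(wake) else NA_real_,
    sleep_mean = if (length(sleep)) mean(sleep) else NA_real_,
    n_wake = length(wake),
    n_sleep = length(sleep)
  )
}
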