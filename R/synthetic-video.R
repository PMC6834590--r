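# Synthetic worm-video rendering with ground-truth centerlines.

#' Configuration for the synthetic worm-video renderer
#'
#' Defaults emulate a single large-chamber recording at the standard
#' behavioral frame rate: a 60-px worm swimming with a traveling body wave
#' in a 64 x 128 px chamber at 3 fps.
#'
#' @param chamber_px Chamber size `(height, width)` in pixels.
#' @param worm_length_px Worm body length (arclength) in pixels; must be
#'   smaller than the larger chamber dimension.
#' @param worm_width_px Rendered body width in pixels.
#' @param fps Frames per second.
#' @param wake_wave Named numeric vector `(amplitude, wavelength, frequency)`
#'   of the traveling sinusoid during wake: amplitude and wavelength in
#'   pixels, frequency in Hz.
#' @param sleep_curvature_gain Dimensionless curvature of the frozen sleep
#'   posture relative to the mean wake curvature (default 1.15: quiescent
#'   animals hold a tighter, hockey-stick-like bend).
#' @param noise_sd Additive Gaussian pixel noise, grey levels (8-bit scale).
#' @param seed Integer seed making rendering bit-reproducible.
#' @return A validated list of class `worm_video_config`.
#' @export
worm_video_config <- function(chamber_px = c(64L, 128L),
                              worm_length_px = 60,
                              worm_width_px = 5,
                              fps = 3,
                              wake_wave = c(amplitude = 6, wavelength = 50,
                                            frequency = 0.5),
                              sleep_curvature_gain = 1.15,
                              noise_sd = 2,
                              seed = 1L) {
  check_number(fps, "fps", min = 0, strict = TRUE, finite = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(worm_length_px, "worm_length_px", min = 0, strict = TRUE)
  if (length(chamber_px) != 2L || any(chamber_px < 8)) {
    abort("`chamber_px` must be (height, width), each >= 8.")
  }
  if (worm_length_px >= max(chamber_px)) {
    abort("`worm_length_px` must be smaller than the larger chamber side.")
  }
  stopifnot(all(c("amplitude", "wavelength", "frequency") %in%
                  names(wake_wave)))
  structure(
    list(chamber_px = as.integer(chamber_px),
         worm_length_px = worm_length_px, worm_width_px = worm_width_px,
         fps = fps, wake_wave = wake_wave,
         sleep_curvature_gain = sleep_curvature_gain,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "worm_video_config"
  )
}

#' Centerline of a traveling sinusoid at a given phase
#'
#' Points `(row, col)` along `y = A sin(2 pi (x / lambda - phase))`, trimmed
#' to arclength `length_px` and centered at the origin.
#' @noRd
wave_centerline <- function(length_px, amplitude, wavelength, phase,
                            n_dense = 241L) {
  xg <- seq(0, 2 * length_px, length.out = 4L * n_dense)
  yg <- amplitude * sin(2 * pi * (xg / wavelength - phase))
  seg <- sqrt(diff(xg)^2 + diff(yg)^2)
  s <- c(0, cumsum(seg))
  target <- seq(0, length_px, length.out = n_dense)
  pts <- cbind(stats::approx(s, yg, xout = target)$y,
               stats::approx(s, xg, xout = target)$y)
  sweep(pts, 2L, colMeans(pts))
}

#' Circular-arc centerline of given arclength and radius, centered at origin
#' @noRd
arc_centerline <- function(length_px, radius, n_dense = 241L) {
  span <- length_px / radius
  th <- seq(-span / 2, span / 2, length.out = n_dense)
  pts <- cbind(radius * sin(th), radius * (1 - cos(th)))
  sweep(pts, 2L, colMeans(pts))
}

#' Rasterize a centerline as a bright anti-aliased thick curve
#' @noRd
rasterize_worm <- function(centerline, dim_hw, width_px, brightness = 255) {
  half <- width_px / 2
  rad <- ceiling(half + 1)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  m <- nrow(centerline)
  k <- nrow(offs)
  pr <- round(centerline[, 1L])
  pc <- round(centerline[, 2L])
  rows <- rep(pr, each = k) + offs$dr
  cols <- rep(pc, each = k) + offs$dc
  dy <- rows - rep(centerline[, 1L], each = k)
  dx <- cols - rep(centerline[, 2L], each = k)
  d <- sqrt(dy^2 + dx^2)
  val <- brightness * pmin(1, pmax(0, half + 0.5 - d))
  ok <- rows >= 1L & rows <= dim_hw[1L] & cols >= 1L & cols <= dim_hw[2L] &
    val > 0
  lin <- (cols[ok] - 1L) * dim_hw[1L] + rows[ok]
  v <- val[ok]
  # max over contributions per pixel
  o <- order(lin, -v)
  lin <- lin[o]; v <- v[o]
  first <- !duplicated(lin)
  img <- matrix(0, dim_hw[1L], dim_hw[2L])
  img[lin[first]] <- v[first]
  img
}

#' Render a synthetic worm video from a bout schedule
#'
#' During wake the worm is a traveling sinusoid advancing every frame;
#' during sleep bouts the centerline freezes in a circular arc whose
#' dimensionless curvature is `sleep_curvature_gain` times the mean wake
#' curvature (measured from the wake centerlines with the same 20-point
#' circle-fit formula the posture module uses). Twitches briefly rock the
#' frozen posture. The worm is drawn as a bright, anti-aliased thick curve
#' of constant brightness on a dark background, with additive Gaussian
#' noise, quantized to 8-bit grey levels.
#'
#' @param config A [worm_video_config()].
#' @param schedule A [bout_schedule()].
#' @return A list with `video` (integer array `[h, w, frames]`), and `truth`
#'   (list: `schedule`, `centerlines` — one dense point matrix per frame —
#'   `asleep`/`twitching` frame indicators, `wake_mean_curvature`,
#'   `sleep_radius_px`).
#' @export
#' @examples
#' sched <- bout_schedule(data.frame(start_s = 20, end_s = 60),
#'                        duration_s = 90)
#' out <- render_worm_video(worm_video_config(fps = 1), sched)
#' dim(out$video)
render_worm_video <- function(config, schedule) {
  stopifnot(inherits(config, "worm_video_config"),
            inherits(schedule, "bout_schedule"))
  hw <- config$chamber_px
  if (config$worm_length_px >= sqrt(sum(hw^2))) {
    abort("Worm is longer than the chamber diagonal.")
  }
  n_frames <- floor(schedule$duration_s * config$fps)
  if (n_frames > 1e6) abort("Recording exceeds 1e6 frames.")
  st <- schedule_state(schedule, config$fps)
  wv <- config$wake_wave
  center <- hw / 2

  # wake centerlines: phase advances continuously with time
  wake_cl <- function(t) {
    cl <- wave_centerline(config$worm_length_px, wv[["amplitude"]],
                          wv[["wavelength"]], wv[["frequency"]] * t)
    sweep(cl, 2L, center, "+")
  }
  # mean wake dimensionless curvature over one full wave period, by the
  # posture module's own 20-point measure
  period_t <- seq(0, 1 / wv[["frequency"]], length.out = 25L)[-25L]
  wake_mean_curv <- mean(vapply(
    period_t,
    function(t) dimensionless_curvature(wake_cl(t)),
    numeric(1L)
  ))
  sleep_radius <- config$worm_length_px /
    (config$sleep_curvature_gain * wake_mean_curv)
  sleep_base <- sweep(arc_centerline(config$worm_length_px, sleep_radius),
                      2L, center, "+")

  video <- array(0L, c(hw[1L], hw[2L], n_frames))
  centerlines <- vector("list", n_frames)
  with_seed_or_not(config$seed, {
    for (i in seq_len(n_frames)) {
      t <- st$time_s[i]
      if (st$asleep[i]) {
        cl <- sleep_base
        if (st$twitching[i]) {
          # small oscillating rigid displacement of the frozen posture
          cl <- sweep(cl, 2L,
                      c(1.5 * sin(2 * pi * 1.5 * t),
                        1.5 * cos(2 * pi * 1.5 * t)), "+")
        }
      } else {
        cl <- wake_cl(t)
      }
      centerlines[[i]] <- cl
      img <- rasterize_worm(cl, hw, config$worm_width_px)
      if (config$noise_sd > 0) {
        img <- img + rnorm(length(img), sd = config$noise_sd)
      }
      video[, , i] <- as.integer(pmin(255, pmax(0, round(img))))
    }
  })
  list(
    video = video,
    truth = list(
      schedule = schedule,
      centerlines = centerlines,
      asleep = st$asleep,
      twitching = st$twitching,
      wake_mean_curvature = wake_mean_curv,
      sleep_radius_px = sleep_radius
    )
  )
}
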