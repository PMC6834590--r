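# Synthetic ground-truth bout schedules and detector-facing activity traces.

#' Construct a bout schedule
#'
#' A bout schedule is the ground truth for a synthetic recording: an ordered
#' set of quiescent (sleep) intervals within `[0, duration_s)`, plus brief
#' twitches (short movements) that occur inside sleep intervals.
#'
#' @param intervals A data frame with columns `start_s`, `end_s` (seconds,
#'   half-open intervals), or `NULL` for none.
#' @param twitches A data frame with columns `time_s`, `duration_s`, or
#'   `NULL` for none. Every twitch must lie inside some sleep interval and
#'   last less than 15 s.
#' @param duration_s Total recording length in seconds.
#' @return An object of class `bout_schedule`: a list with tibbles
#'   `intervals` and `twitches` and the scalar `duration_s`.
#' @export
#' @examples
#' bout_schedule(data.frame(start_s = 60, end_s = 180), duration_s = 600)
bout_schedule <- function(intervals = NULL, twitches = NULL, duration_s) {
  check_number(duration_s, "duration_s", min = 0, strict = TRUE, finite = TRUE)
  intervals <- if (is.null(intervals) || nrow(intervals) == 0L) {
    tibble(start_s = numeric(), end_s = numeric())
  } else {
    as_tibble(intervals[c("start_s", "end_s")])
  }
  twitches <- if (is.null(twitches) || nrow(twitches) == 0L) {
    tibble(time_s = numeric(), duration_s = numeric())
  } else {
    as_tibble(twitches[c("time_s", "duration_s")])
  }
  if (nrow(intervals) > 0L) {
    intervals <- dplyr::arrange(intervals, .data$start_s)
    if (any(intervals$end_s <= intervals$start_s)) {
      abort("Every interval must satisfy end_s > start_s.")
    }
    if (any(intervals$start_s < 0) || any(intervals$end_s > duration_s)) {
      abort("Intervals must be contained in [0, duration_s].")
    }
    if (nrow(intervals) > 1L &&
        any(intervals$start_s[-1L] < intervals$end_s[-nrow(intervals)])) {
      abort("Intervals must be non-overlapping.")
    }
  }
  if (nrow(twitches) > 0L) {
    if (any(twitches$duration_s >= 15)) {
      abort("Twitches must last less than 15 s.")
    }
    inside <- purrr::map2_lgl(
      twitches$time_s, twitches$duration_s,
      function(t0, d) {
        any(intervals$start_s <= t0 & (t0 + d) <= intervals$end_s)
      }
    )
    if (!all(inside)) {
      abort("Every twitch must lie inside a sleep interval.")
    }
    twitches <- dplyr::arrange(twitches, .data$time_s)
  }
  structure(
    list(intervals = intervals, twitches = twitches, duration_s = duration_s),
    class = "bout_schedule"
  )
}

#' @export
print.bout_schedule <- function(x, ...) {
  cat(sprintf(
    "<bout_schedule> %.0f s, %d sleep interval(s) (%.0f s total), %d twitch(es)\n",
    x$duration_s, nrow(x$intervals),
    sum(x$intervals$end_s - x$intervals$start_s), nrow(x$twitches)
  ))
  invisible(x)
}

#' Sample a random wake/sleep bout schedule
#'
#' Draws an alternating wake/sleep state sequence. Wake durations are
#' exponential with mean `mean_wake_s`; sleep durations are exponential with
#' mean `mean_sleep_s` truncated below at `min_bout_s` (equivalently
#' `min_bout_s` plus an exponential of mean `mean_sleep_s`, so the expected
#' sleep-bout length is `min_bout_s + mean_sleep_s`). Twitches are placed by
#' a Poisson process restricted to sleep intervals at `twitch_rate_per_min`
#' events per minute of sleep, each lasting `runif(1, 10)` seconds; twitch
#' onsets within one interval are thinned to at least 30 s apart so distinct
#' twitches remain distinct events after 20-s smoothing.
#'
#' @param duration_s Recording length in seconds.
#' @param mean_sleep_s Mean of the (untruncated) sleep-duration exponential.
#' @param mean_wake_s Mean wake duration in seconds.
#' @param min_bout_s Lower truncation of sleep durations (default 30 s, the
#'   minimum bout length used in detection).
#' @param twitch_rate_per_min Twitch rate per minute of sleep.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [bout_schedule()].
#' @export
#' @examples
#' sched <- sample_bout_schedule(3600, seed = 1)
#' nrow(sched$intervals)
sample_bout_schedule <- function(duration_s,
                                 mean_sleep_s = 360,
                                 mean_wake_s = 240,
                                 min_bout_s = 30,
                                 twitch_rate_per_min = 0.5,
                                 seed = NULL) {
  check_number(duration_s, "duration_s", min = 0, strict = TRUE, finite = TRUE)
  check_number(mean_sleep_s, "mean_sleep_s", min = 0, strict = TRUE)
  check_number(mean_wake_s, "mean_wake_s", min = 0, strict = TRUE)
  check_number(min_bout_s, "min_bout_s", min = 0, strict = TRUE, finite = TRUE)
  check_number(twitch_rate_per_min, "twitch_rate_per_min", min = 0)
  if (min_bout_s > mean_sleep_s) {
    abort("`min_bout_s` must not exceed `mean_sleep_s`.")
  }
  with_seed_or_not(seed, {
    t0 <- 0
    starts <- numeric()
    ends <- numeric()
    repeat {
      wake <- rexp(1L, rate = 1 / mean_wake_s)
      t0 <- t0 + wake
      if (t0 >= duration_s) break
      sleep <- min_bout_s + rexp(1L, rate = 1 / mean_sleep_s)
      t1 <- min(t0 + sleep, duration_s)
      starts <- c(starts, t0)
      ends <- c(ends, t1)
      t0 <- t1
      if (t0 >= duration_s) break
    }
    intervals <- tibble(start_s = starts, end_s = ends)
    twitches <- tibble(time_s = numeric(), duration_s = numeric())
    if (twitch_rate_per_min > 0 && nrow(intervals) > 0L) {
      rate_s <- twitch_rate_per_min / 60
      tw <- purrr::pmap_dfr(intervals, function(start_s, end_s) {
        len <- end_s - start_s
        n <- rpois(1L, rate_s * len)
        if (n == 0L) return(tibble(time_s = numeric(), duration_s = numeric()))
        times <- sort(runif(n, start_s, end_s))
        durs <- runif(n, 1, 10)
        # thin: keep onsets >= 30 s apart, and fit inside the interval
        keep <- logical(n)
        last <- -Inf
        for (i in seq_len(n)) {
          if (times[i] - last >= 30 && times[i] + durs[i] <= end_s) {
            keep[i] <- TRUE
            last <- times[i]
          }
        }
        tibble(time_s = times[keep], duration_s = durs[keep])
      })
      twitches <- tw
    }
    bout_schedule(intervals, twitches, duration_s)
  })
}

#' Per-frame state indicators for a schedule
#'
#' Rasterizes a [bout_schedule()] to frame resolution: frame `i` (0-based)
#' covers time `[i/fps, (i+1)/fps)` and is labeled by its start time.
#'
#' @param schedule A [bout_schedule()].
#' @param fps Frames per second.
#' @return A tibble with columns `frame` (0-based), `time_s`, `asleep`
#'   (logical), `twitching` (logical).
#' @export
schedule_state <- function(schedule, fps) {
  check_number(fps, "fps", min = 0, strict = TRUE, finite = TRUE)
  n <- floor(schedule$duration_s * fps)
  time_s <- (seq_len(n) - 1L) / fps
  asleep <- rep(FALSE, n)
  for (i in seq_len(nrow(schedule$intervals))) {
    asleep <- asleep |
      (time_s >= schedule$intervals$start_s[i] &
         time_s < schedule$intervals$end_s[i])
  }
  twitching <- rep(FALSE, n)
  for (i in seq_len(nrow(schedule$twitches))) {
    twitching <- twitching |
      (time_s >= schedule$twitches$time_s[i] &
         time_s < schedule$twitches$time_s[i] + schedule$twitches$duration_s[i])
  }
  tibble(frame = seq_len(n) - 1L, time_s = time_s,
         asleep = asleep, twitching = twitching)
}

#' Synthesize a raw activity trace from a bout schedule
#'
#' Emulates the frame-subtraction pixel-count signal of a real recording:
#' during wake the count fluctuates around `wake_level`; during sleep it sits
#' near `sleep_level`; twitches produce brief bursts at
#' `twitch_frac * wake_level`, i.e. low-activity movement well below full
#' wake locomotion.
#'
#' @param schedule A [bout_schedule()].
#' @param fps Frames per second (default 3, the standard behavioral rate).
#' @param wake_level Mean changed-pixel count during wake.
#' @param sleep_level Mean count during sleep (sensor noise floor).
#' @param twitch_frac Twitch activity as a fraction of `wake_level`.
#' @param noise_frac Wake noise standard deviation as a fraction of
#'   `wake_level`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A tibble with columns `frame` (0-based frame-pair index),
#'   `time_s`, and `raw` (non-negative integer counts); length
#'   `floor(duration_s * fps) - 1` to mirror a frame-pair series.
#' @export
schedule_activity_trace <- function(schedule,
                                    fps = 3,
                                    wake_level = 300,
                                    sleep_level = 2,
                                    twitch_frac = 0.35,
                                    noise_frac = 0.05,
                                    seed = NULL) {
  st <- schedule_state(schedule, fps)
  st <- st[-nrow(st), ]  # frame pairs: one fewer than frames
  with_seed_or_not(seed, {
    n <- nrow(st)
    level <- ifelse(st$asleep, sleep_level, wake_level)
    level[st$twitching] <- twitch_frac * wake_level
    sdev <- ifelse(st$asleep & !st$twitching, 1, noise_frac * wake_level)
    raw <- pmax(0, round(rnorm(n, mean = level, sd = sdev)))
    tibble(frame = st$frame, time_s = st$time_s, raw = raw)
  })
}
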