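# Quiescent-bout detection and bout statistics.

#' Sleep-detection threshold for a chamber geometry
#'
#' Normalized-activity thresholds below which an animal is considered
#' quiescent. Thresholds depend on how strongly the geometry constrains
#' movement: the more confined the animal, the lower the residual wake
#' activity and the stricter the threshold. The `ris_50um` label is the
#' two-color RIS imaging configuration, where behavior is quantified on a
#' high-dynamic-range sensor and a looser threshold of 0.2 applies.
#'
#' @param geometry One of `"wormotel"`, `"chamber_500um"`, `"chamber_110um"`,
#'   `"chamber_50um"`, `"ris_50um"`.
#' @return The normalized activity threshold (dimensionless).
#' @export
#' @examples
#' geometry_threshold("chamber_110um")
geometry_threshold <- function(geometry) {
  thresholds <- c(
    wormotel = 0.15,
    chamber_500um = 0.15,
    chamber_110um = 0.08,
    chamber_50um = 0.06,
    ris_50um = 0.2
  )
  if (!is.character(geometry) || length(geometry) != 1L ||
      !geometry %in% names(thresholds)) {
    abort(paste0(
      "Unknown geometry. Valid labels: ",
      paste(names(thresholds), collapse = ", "), "."
    ))
  }
  unname(thresholds[[geometry]])
}

new_bout_set <- function(bouts, animal_id, fps, threshold, min_bout_s,
                         max_twitch_s, recording_s) {
  out <- as_tibble(bouts)
  attr(out, "animal_id") <- animal_id
  attr(out, "fps") <- fps
  attr(out, "threshold") <- threshold
  attr(out, "min_bout_s") <- min_bout_s
  attr(out, "max_twitch_s") <- max_twitch_s
  attr(out, "recording_s") <- recording_s
  class(out) <- c("bout_set", class(out))
  out
}

#' Detect quiescent bouts in a normalized activity trace
#'
#' Frames with activity strictly below `threshold` are candidate-quiescent.
#' Candidate runs separated by supra-threshold gaps strictly shorter than
#' `max_twitch_s` are merged first (brief twitching during sleep does not
#' count as wake); merged runs shorter than `min_bout_s` are then discarded
#' (reduces false detections). Merging precedes the minimum-duration filter
#' so that a long bout interrupted by a single twitch survives as a unit. A
#' bout truncated by the end of the recording is kept if its observed length
#' reaches `min_bout_s`.
#'
#' @param normalized Numeric vector of normalized activity (one value per
#'   frame pair; index `i` covers time `[(i-1)/fps, i/fps)`).
#' @param fps Frames per second.
#' @param threshold Quiescence threshold; see [geometry_threshold()].
#' @param min_bout_s Minimum bout duration in seconds (default 30).
#' @param max_twitch_s Maximum interruption merged into a bout (default 15).
#' @param animal_id Identifier stored on the result.
#' @param recording_s Recording length in seconds; defaults to
#'   `length(normalized) / fps`.
#' @return A `bout_set`: a tibble with columns `start_s`, `end_s` (half-open
#'   intervals at frame resolution), carrying the detection parameters as
#'   attributes. Use [tidy()] / [glance()] / [bout_statistics()] on it.
#' @export
#' @examples
#' act <- rep(c(1, 0, 1), c(90, 135, 90))  # 45 s of quiescence at 3 fps
#' detect_bouts(act, fps = 3, threshold = 0.15)
detect_bouts <- function(normalized, fps, threshold,
                         min_bout_s = 30, max_twitch_s = 15,
                         animal_id = "animal1", recording_s = NULL) {
  check_number(fps, "fps", min = 0, strict = TRUE, finite = TRUE)
  check_number(threshold, "threshold", min = 0, strict = TRUE)
  check_number(min_bout_s, "min_bout_s", min = 0, strict = TRUE)
  check_number(max_twitch_s, "max_twitch_s", min = 0)
  if (anyNA(normalized)) abort("`normalized` contains NA/NaN activity.")
  recording_s <- recording_s %||% (length(normalized) / fps)
  empty <- tibble(start_s = numeric(), end_s = numeric())
  if (length(normalized) == 0L) {
    return(new_bout_set(empty, animal_id, fps, threshold, min_bout_s,
                        max_twitch_s, recording_s))
  }
  runs <- true_runs(normalized < threshold)
  if (nrow(runs) > 1L) {
    # merge runs across sub-max_twitch_s gaps
    gap_s <- (runs$start[-1L] - runs$end[-nrow(runs)]) / fps
    first_of_group <- which(c(TRUE, gap_s >= max_twitch_s))
    last_of_group <- c(first_of_group[-1L] - 1L, nrow(runs))
    runs <- tibble(
      start = runs$start[first_of_group],
      end = runs$end[last_of_group]
    )
  }
  len_s <- (runs$end - runs$start) / fps
  runs <- runs[len_s >= min_bout_s, , drop = FALSE]
  bouts <- tibble(
    start_s = (runs$start - 1L) / fps,  # frame indices are 0-based in time
    end_s = (runs$end - 1L) / fps
  )
  new_bout_set(bouts, animal_id, fps, threshold, min_bout_s, max_twitch_s,
               recording_s)
}

#' @export
print.bout_set <- function(x, ...) {
  cat(sprintf(
    "<bout_set> %s: %d bout(s), %.1f / %.0f s asleep (threshold %.3g)\n",
    attr(x, "animal_id"), nrow(x), sum(x$end_s - x$start_s),
    attr(x, "recording_s"), attr(x, "threshold")
  ))
  NextMethod()
}

#' Tidy a bout set into a plain interval table
#'
#' @param x A `bout_set` from [detect_bouts()].
#' @param ... Unused.
#' @return A tibble with `animal_id`, `bout`, `start_s`, `end_s`,
#'   `duration_s`.
#' @method tidy bout_set
#' @export
tidy.bout_set <- function(x, ...) {
  tibble(
    animal_id = attr(x, "animal_id"),
    bout = seq_len(nrow(x)),
    start_s = x$start_s,
    end_s = x$end_s,
    duration_s = x$end_s - x$start_s
  )
}

#' One-row summary of a bout set
#'
#' @param x A `bout_set` from [detect_bouts()].
#' @param ... Unused.
#' @return A one-row tibble: `animal_id`, `n_bouts`, `total_sleep_s`,
#'   `sleep_fraction`, `onset_s`, `recording_s`.
#' @method glance bout_set
#' @export
glance.bout_set <- function(x, ...) {
  total <- sum(x$end_s - x$start_s)
  tibble(
    animal_id = attr(x, "animal_id"),
    n_bouts = nrow(x),
    total_sleep_s = total,
    sleep_fraction = total / attr(x, "recording_s"),
    onset_s = if (nrow(x) > 0L) x$start_s[1L] else NA_real_,
    recording_s = attr(x, "recording_s")
  )
}

#' Bout statistics for one animal
#'
#' Computes the per-animal quantities used in group comparisons: total sleep
#' and sleep fraction, onset of the first bout, individual sleep-bout
#' lengths, wake-bout lengths (gaps between consecutive bouts plus the
#' terminal gap, explicitly excluding the first period of wake before any
#' sleep), and homeostasis pairs matching each sleep bout with the length of
#' the wake bout immediately preceding it (the first bout, which has no
#' preceding wake bout inside the recording, is excluded).
#'
#' @param bouts A `bout_set` from [detect_bouts()].
#' @return A one-row tibble: scalar columns `animal_id`, `recording_s`,
#'   `n_bouts`, `total_sleep_s`, `sleep_fraction`, `onset_s`; list-columns
#'   `sleep_bout_lengths_s`, `wake_bout_lengths_s`, `homeostasis_pairs`
#'   (a tibble with `preceding_wake_s`, `sleep_bout_s`).
#' @export
#' @examples
#' act <- rep(c(1, 0, 1, 0, 1), c(300, 180, 720, 270, 9330)) / 1
#' b <- detect_bouts(act, fps = 3, threshold = 0.15)
#' bout_statistics(b)
bout_statistics <- function(bouts) {
  if (!inherits(bouts, "bout_set")) abort("`bouts` must be a bout_set.")
  recording_s <- attr(bouts, "recording_s")
  n <- nrow(bouts)
  sleep_lengths <- bouts$end_s - bouts$start_s
  wake_lengths <- numeric()
  pairs <- tibble(preceding_wake_s = numeric(), sleep_bout_s = numeric())
  if (n > 0L) {
    inter <- if (n > 1L) bouts$start_s[-1L] - bouts$end_s[-n] else numeric()
    terminal <- recording_s - bouts$end_s[n]
    wake_lengths <- c(inter, if (terminal > 0) terminal)
    if (n > 1L) {
      pairs <- tibble(preceding_wake_s = inter,
                      sleep_bout_s = sleep_lengths[-1L])
    }
  }
  tibble(
    animal_id = attr(bouts, "animal_id"),
    recording_s = recording_s,
    n_bouts = n,
    total_sleep_s = sum(sleep_lengths),
    sleep_fraction = sum(sleep_lengths) / recording_s,
    onset_s = if (n > 0L) bouts$start_s[1L] else NA_real_,
    sleep_bout_lengths_s = list(sleep_lengths),
    wake_bout_lengths_s = list(wake_lengths),
    homeostasis_pairs = list(pairs)
  )
}

#' Sensitivity of bout statistics to the minimum-bout setting
#'
#' Reruns detection and summary statistics across a grid of `min_bout_s`
#' values, mirroring the robustness check that headline results should not
#' depend on the choice of minimum bout duration.
#'
#' @inheritParams detect_bouts
#' @param min_bout_grid Numeric vector of minimum bout durations to try
#'   (default `c(15, 30, 60)`).
#' @return A tibble with one row per grid value: `min_bout_s` plus the
#'   [glance.bout_set()] columns.
#' @export
bout_sensitivity <- function(normalized, fps, threshold,
                             min_bout_grid = c(15, 30, 60),
                             max_twitch_s = 15, animal_id = "animal1",
                             recording_s = NULL) {
  purrr::map_dfr(min_bout_grid, function(mb) {
    b <- detect_bouts(normalized, fps, threshold, mb, max_twitch_s,
                      animal_id, recording_s)
    dplyr::bind_cols(tibble(min_bout_s = mb), glance(b))
  })
}
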