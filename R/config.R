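# Experiment configuration: every tunable analysis parameter in one place.

#' Build a validated experiment configuration
#'
#' Collects the analysis parameters for one recording. Defaults are the
#' standard values for behavioral imaging: 3 fps, a 30-grey-level pixel
#' change threshold, 20-s smoothing, 95th-percentile normalization, a
#' geometry-specific sleep threshold, 30-s minimum bouts and 15-s twitch
#' tolerance. The `ris_50um` geometry switches to the two-color RIS setup
#' (0.5 fps, pixel threshold 400, sleep threshold 0.2).
#'
#' @param geometry Chamber geometry label; see [geometry_threshold()].
#' @param fps Frames per second.
#' @param pixel_delta_threshold Grey-level change counting as movement.
#' @param smoothing_window_s Activity smoothing window (seconds).
#' @param norm_percentile Normalization percentile.
#' @param sleep_threshold Normalized-activity sleep threshold; defaults to
#'   [geometry_threshold()] of `geometry`.
#' @param min_bout_s Minimum sleep-bout duration (seconds).
#' @param max_twitch_s Maximum merged interruption (seconds).
#' @param stim_times_s Optional stimulus schedule (seconds).
#' @param seed Integer seed recorded for synthetic runs.
#' @return A validated list of class `experiment_config`.
#' @export
#' @examples
#' experiment_config("chamber_110um")$sleep_threshold  # 0.08
experiment_config <- function(geometry = "chamber_500um",
                              fps = if (geometry == "ris_50um") 0.5 else 3,
                              pixel_delta_threshold =
                                if (geometry == "ris_50um") 400 else 30,
                              smoothing_window_s = 20,
                              norm_percentile = 95,
                              sleep_threshold = geometry_threshold(geometry),
                              min_bout_s = 30,
                              max_twitch_s = 15,
                              stim_times_s = NULL,
                              seed = 1L) {
  check_number(fps, "fps", min = 0, strict = TRUE, finite = TRUE)
  check_number(pixel_delta_threshold, "pixel_delta_threshold",
               min = 0, strict = TRUE)
  check_number(smoothing_window_s, "smoothing_window_s", min = 0)
  check_number(norm_percentile, "norm_percentile", min = 0, strict = TRUE)
  if (norm_percentile > 100) abort("`norm_percentile` must be <= 100.")
  check_number(sleep_threshold, "sleep_threshold", min = 0, strict = TRUE)
  check_number(min_bout_s, "min_bout_s", min = 0, strict = TRUE)
  check_number(max_twitch_s, "max_twitch_s", min = 0)
  geometry_threshold(geometry)  # validates the label
  structure(
    list(geometry = geometry, fps = fps,
         pixel_delta_threshold = pixel_delta_threshold,
         smoothing_window_s = smoothing_window_s,
         norm_percentile = norm_percentile,
         sleep_threshold = sleep_threshold,
         min_bout_s = min_bout_s, max_twitch_s = max_twitch_s,
         stim_times_s = stim_times_s, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Unknown fields raise an error; missing fields fall back to the
#' [experiment_config()] defaults, so a config file only needs to state
#' what differs from the standard protocol.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(experiment_config)), "...")
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    abort(paste0("Unknown config field(s): ", paste(extra, collapse = ", ")))
  }
  do.call(experiment_config, raw)
}

#' Run the activity-to-bouts pipeline under one configuration
#'
#' Convenience wrapper: video in, activity trace and bout set out, using
#' the thresholds of the configured geometry.
#'
#' @param video Integer array `[height, width, frames]`.
#' @param config An [experiment_config()].
#' @param roi Optional [roi_rect()].
#' @return A list with `trace` (tibble) and `bouts` (`bout_set`).
#' @export
analyze_video <- function(video, config = experiment_config(), roi = NULL) {
  trace <- activity_trace(
    video, roi, config$fps,
    pixel_delta_threshold = config$pixel_delta_threshold,
    smoothing_window_s = config$smoothing_window_s,
    norm_percentile = config$norm_percentile
  )
  bouts <- detect_bouts(
    trace$normalized, config$fps, config$sleep_threshold,
    config$min_bout_s, config$max_twitch_s,
    animal_id = trace$animal_id[1L]
  )
  list(trace = trace, bouts = bouts)
}
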