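# Frame-by-frame subtraction activity quantification.

#' Rectangular region of interest
#'
#' Pixel bounds are 0-based and half-open, so `roi_rect(0, 0, h, w)` covers a
#' whole `h x w` frame.
#'
#' @param row0,col0 Inclusive upper-left corner (0-based).
#' @param row1,col1 Exclusive lower-right corner.
#' @param animal_id Identifier attached to downstream traces.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(row0, col0, row1, col1, animal_id = "animal1") {
  if (row1 <= row0 || col1 <= col0) {
    abort("ROI must have positive extent (row1 > row0, col1 > col0).")
  }
  if (row0 < 0 || col0 < 0) abort("ROI bounds must be non-negative.")
  structure(
    list(row0 = as.integer(row0), col0 = as.integer(col0),
         row1 = as.integer(row1), col1 = as.integer(col1),
         animal_id = animal_id),
    class = "roi_rect"
  )
}

roi_indices <- function(roi, dim_hw) {
  if (roi$row1 > dim_hw[1L] || roi$col1 > dim_hw[2L]) {
    abort("ROI exceeds frame bounds.")
  }
  list(rows = (roi$row0 + 1L):roi$row1, cols = (roi$col0 + 1L):roi$col1)
}

#' Raw activity by frame-by-frame subtraction
#'
#' Counts, for every consecutive frame pair, the pixels inside the ROI whose
#' grey value changes by strictly more than `pixel_delta_threshold`.
#' Differences are taken on signed values, so unsigned 8-bit input cannot
#' wrap around. The default threshold of 30 grey levels suits 8-bit CMOS
#' behavioral video; two-channel RIS recordings on a 16-bit sensor use 400
#' (see [experiment_config()]).
#'
#' @param video Integer array `[height, width, frames]` with at least two
#'   frames.
#' @param roi A [roi_rect()], or `NULL` for the full frame.
#' @param pixel_delta_threshold Grey-level change that counts as movement
#'   (strict inequality).
#' @return Numeric vector of length `frames - 1`: changed-pixel counts per
#'   frame pair.
#' @export
#' @examples
#' vid <- array(0L, c(4, 4, 3))
#' vid[1, 1:3, 2] <- 100L
#' frame_difference_activity(vid)  # 3 pixels change into frame 2, then back
frame_difference_activity <- function(video, roi = NULL,
                                      pixel_delta_threshold = 30) {
  d <- dim(video)
  if (length(d) != 3L || d[3L] < 2L) {
    abort("`video` must be a [height, width, frames] array with >= 2 frames.")
  }
  check_number(pixel_delta_threshold, "pixel_delta_threshold",
               min = 0, strict = TRUE)
  if (is.null(roi)) roi <- roi_rect(0L, 0L, d[1L], d[2L])
  ix <- roi_indices(roi, d)
  sub <- video[ix$rows, ix$cols, , drop = FALSE]
  storage.mode(sub) <- "double"  # widen before subtraction
  npx <- length(ix$rows) * length(ix$cols)
  m <- matrix(sub, nrow = npx)
  delta <- abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  unname(colSums(delta > pixel_delta_threshold))
}

#' Smooth and normalize a raw activity series
#'
#' Applies a centered moving average over `smoothing_window_s` seconds
#' (window truncated at the edges; `smoothing_window_s = 0` skips smoothing,
#' used for fine-timescale stimulus analysis), then divides by the
#' `norm_percentile`-th percentile of the smoothed series (linear
#' interpolation between order statistics). Values are approximately in
#' `[0, 1]`; the top tail may exceed 1 and is not clipped.
#'
#' @param raw Numeric vector of raw activity (changed-pixel counts).
#' @param fps Frames per second of the underlying video.
#' @param smoothing_window_s Smoothing window in seconds (default 20).
#' @param norm_percentile Normalization percentile (default 95).
#' @return Numeric vector, same length as `raw`.
#' @export
normalize_activity <- function(raw, fps, smoothing_window_s = 20,
                               norm_percentile = 95) {
  if (length(raw) == 0L) abort("`raw` must be non-empty.")
  if (anyNA(raw)) abort("`raw` must not contain NA.")
  check_number(fps, "fps", min = 0, strict = TRUE, finite = TRUE)
  check_number(smoothing_window_s, "smoothing_window_s", min = 0)
  check_number(norm_percentile, "norm_percentile", min = 0, strict = TRUE)
  if (norm_percentile > 100) abort("`norm_percentile` must be <= 100.")
  smoothed <- if (smoothing_window_s > 0) {
    moving_average(raw, window_frames(smoothing_window_s, fps))
  } else {
    raw
  }
  denom <- percentile(smoothed, norm_percentile)
  if (denom <= 0) {
    abort(paste0(
      "Degenerate trace: the ", norm_percentile,
      "th percentile of the smoothed activity is not positive."
    ))
  }
  smoothed / denom
}

#' Full activity trace for one animal
#'
#' Convenience wrapper chaining [frame_difference_activity()] and
#' [normalize_activity()] into a tidy per-frame-pair table.
#'
#' @inheritParams frame_difference_activity
#' @inheritParams normalize_activity
#' @param fps Frames per second.
#' @return A tibble with columns `animal_id`, `frame` (0-based frame-pair
#'   index), `time_s`, `raw`, `normalized`, carrying the processing
#'   parameters as attributes `fps`, `smoothing_window_s`,
#'   `pixel_delta_threshold`, `norm_percentile`.
#' @export
activity_trace <- function(video, roi = NULL, fps = 3,
                           pixel_delta_threshold = 30,
                           smoothing_window_s = 20,
                           norm_percentile = 95) {
  raw <- frame_difference_activity(video, roi, pixel_delta_threshold)
  normalized <- normalize_activity(raw, fps, smoothing_window_s,
                                   norm_percentile)
  out <- tibble(
    animal_id = if (is.null(roi)) "animal1" else roi$animal_id,
    frame = seq_along(raw) - 1L,
    time_s = (seq_along(raw) - 1L) / fps,
    raw = raw,
    normalized = normalized
  )
  attr(out, "fps") <- fps
  attr(out, "smoothing_window_s") <- smoothing_window_s
  attr(out, "pixel_delta_threshold") <- pixel_delta_threshold
  attr(out, "norm_percentile") <- norm_percentile
  out
}
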