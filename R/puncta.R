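# Size-gated counting of bright nuclear puncta (DAF-16::GFP style).

#' Default puncta contrast-enhancement kernel
#'
#' A 3x3 sharpening kernel with unit DC gain: the identity plus a zero-sum
#' Laplacian boost (center 17/9, neighbors -1/9). Uniform regions pass
#' through unchanged while small bright objects gain contrast, so the pixel
#' area of a punctum is preserved and large uniform blobs are not reduced
#' to their edge rings (which would defeat the size gate).
#'
#' @return A 3x3 numeric matrix.
#' @export
puncta_highpass_kernel <- function() {
  k <- matrix(-1 / 9, 3L, 3L)
  k[2L, 2L] <- 17 / 9
  k
}

#' Count size-gated puncta in one frame
#'
#' Pipeline: subtract the background image (clamped at 0); median-filter
#' (3x3) and threshold (Otsu) to find the animal body and draw its bounding
#' ROI; within the ROI, sharpen with the 3x3 contrast kernel, binarize at
#' `mean + binarize_k * sd` of the filtered ROI, label 8-connected
#' components, and count those whose pixel area lies in
#' `[min_area_px, max_area_px]`.
#'
#' By default the sharpening filter runs on the background-subtracted image
#' rather than the median-filtered one: a 3x3 median erases objects at the
#' small end of the 2-px size gate, so the median is used only to
#' stabilize body detection. Set `highpass_on_smoothed = TRUE` to sharpen
#' the median-filtered image instead.
#'
#' @param frame Numeric matrix (one captured frame).
#' @param background Numeric matrix recorded with no animals, or `NULL`.
#' @param min_area_px,max_area_px Inclusive object-size gate in pixels
#'   (defaults 2 and 30).
#' @param kernel 3x3 sharpening kernel (default [puncta_highpass_kernel()]).
#' @param binarize_k Binarization threshold in ROI standard deviations
#'   above the ROI mean (default 3).
#' @param highpass_on_smoothed Sharpen the median-filtered image instead of
#'   the raw subtraction (default `FALSE`).
#' @return Integer count. The labeled component table (area and centroid of
#'   every supra-threshold object, gated or not) is attached as attribute
#'   `"components"`.
#' @export
count_puncta_frame <- function(frame, background = NULL,
                               min_area_px = 2L, max_area_px = 30L,
                               kernel = puncta_highpass_kernel(),
                               binarize_k = 3,
                               highpass_on_smoothed = FALSE) {
  if (!is.null(background)) {
    if (!all(dim(frame) == dim(background))) {
      abort("`frame` and `background` must have the same shape.")
    }
    frame <- pmax(frame - background, 0)
  }
  frame <- frame * 1.0
  med <- median_filter_3x3(frame)
  # clip the brightest tail so rare puncta do not dominate the body split
  body <- med > otsu_threshold(pmin(med, percentile(med, 95)))
  lab <- label_components_8(body)
  if (max(lab) == 0L) abort("Empty ROI: no animal body detected.")
  sizes <- tabulate(lab[lab > 0L])
  body_idx <- which(lab == which.max(sizes), arr.ind = TRUE)
  r0 <- min(body_idx[, 1L]); r1 <- max(body_idx[, 1L])
  c0 <- min(body_idx[, 2L]); c1 <- max(body_idx[, 2L])
  src <- if (highpass_on_smoothed) med else frame
  hp <- filter_3x3(src, kernel)[r0:r1, c0:c1]
  thr <- mean(hp) + binarize_k * sd(hp)
  mask <- hp > thr
  labs <- label_components_8(mask)
  comps <- if (max(labs) > 0L) {
    areas <- tabulate(labs[labs > 0L])
    idx <- which(labs > 0L, arr.ind = TRUE)
    grp <- factor(labs[labs > 0L], levels = seq_along(areas))
    tibble(
      component = seq_along(areas),
      area_px = areas,
      row = as.numeric(tapply(idx[, 1L], grp, mean)) + r0 - 1,
      col = as.numeric(tapply(idx[, 2L], grp, mean)) + c0 - 1
    )
  } else {
    tibble(component = integer(), area_px = integer(),
           row = numeric(), col = numeric())
  }
  count <- sum(comps$area_px >= min_area_px & comps$area_px <= max_area_px)
  structure(count, components = comps)
}

#' Aggregate per-frame puncta counts for one timepoint
#'
#' Animal movement blurs some of the frames captured in each burst and
#' depresses their counts, so the reported count for a timepoint is the
#' mean of the 3 largest per-frame counts out of the burst of 7.
#'
#' @param per_frame_counts Integer vector of per-frame counts (7 expected;
#'   fewer are accepted with a warning, using the top 3 of what is there).
#' @param n_top Number of largest counts averaged (default 3).
#' @return The reported count (numeric scalar).
#' @export
#' @examples
#' aggregate_timepoint(c(1, 2, 3, 4, 5, 6, 7))  # (7 + 6 + 5) / 3
aggregate_timepoint <- function(per_frame_counts, n_top = 3L) {
  if (length(per_frame_counts) == 0L) abort("No per-frame counts given.")
  if (length(per_frame_counts) < 7L) {
    warn(sprintf("Only %d frame count(s) supplied (7 expected).",
                 length(per_frame_counts)))
  }
  top <- sort(per_frame_counts, decreasing = TRUE)
  mean(top[seq_len(min(n_top, length(top)))])
}

#' Puncta counts for a burst of frames
#'
#' Applies [count_puncta_frame()] to each frame of a timepoint burst and
#' aggregates with [aggregate_timepoint()].
#'
#' @param frames List of frame matrices (typically 7).
#' @param background Background matrix or `NULL`.
#' @param animal_id,timepoint_s Identifiers stored on the result.
#' @param ... Passed to [count_puncta_frame()].
#' @return A one-row tibble: `animal_id`, `timepoint_s`, `reported_count`,
#'   and the list-column `per_frame_counts`.
#' @export
puncta_timepoint <- function(frames, background = NULL,
                             animal_id = "animal1", timepoint_s = 0, ...) {
  counts <- purrr::map_int(frames, function(f) {
    as.integer(count_puncta_frame(f, background, ...))
  })
  tibble(
    animal_id = animal_id,
    timepoint_s = timepoint_s,
    reported_count = aggregate_timepoint(counts),
    per_frame_counts = list(counts)
  )
}
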