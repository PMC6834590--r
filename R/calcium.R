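# Fluorescence-trace processing: ROI extraction, dF/F, ratiometric dR/R,
# displacement-based behavior, and behavior-fluorescence correlation.

#' Mean-intensity trace of a square neuron ROI
#'
#' `F(t)` is the mean pixel value in a square ROI of side `2 * roi_half_px`
#' centered on `center` in every frame (default 8 x 8, the standard
#' single-neuron ROI for nuclear GCaMP at 40x).
#'
#' @param video Array `[height, width, frames]`.
#' @param center Numeric `(row, col)` ROI center (1-based pixel coords).
#' @param roi_half_px Half the ROI side length (default 4).
#' @return Numeric vector `F` of per-frame mean intensities.
#' @export
extract_neuron_trace <- function(video, center, roi_half_px = 4L) {
  d <- dim(video)
  r0 <- round(center[1L]) - roi_half_px + 1L
  r1 <- round(center[1L]) + roi_half_px
  c0 <- round(center[2L]) - roi_half_px + 1L
  c1 <- round(center[2L]) + roi_half_px
  if (r0 < 1L || c0 < 1L || r1 > d[1L] || c1 > d[2L]) {
    abort("Neuron ROI is clipped by the frame edge.")
  }
  sub <- video[r0:r1, c0:c1, , drop = FALSE]
  apply(sub, 3L, mean)
}

#' Soma fluorescence as the mean of the brightest pixels in a window
#'
#' Draws a `window_px x window_px` ROI around the soma centroid and returns
#' the mean of the `n_top` largest pixel values (default: top 20 of a
#' 25 x 25 window), which makes the readout robust to small centroid errors
#' and to the soma occupying only part of the window. Windows clipped by the
#' frame edge are truncated with a warning.
#'
#' @param frame Numeric matrix (one channel, one frame).
#' @param soma_centroid Numeric `(row, col)`, 1-based.
#' @param window_px Window side length (default 25).
#' @param n_top Number of brightest pixels averaged (default 20).
#' @return Scalar fluorescence value.
#' @export
extract_ris_trace <- function(frame, soma_centroid, window_px = 25L,
                              n_top = 20L) {
  half <- (window_px - 1L) %/% 2L
  r <- round(soma_centroid[1L]); cc <- round(soma_centroid[2L])
  r0 <- r - half; r1 <- r + (window_px - 1L - half)
  c0 <- cc - half; c1 <- cc + (window_px - 1L - half)
  if (r0 < 1L || c0 < 1L || r1 > nrow(frame) || c1 > ncol(frame)) {
    warn("RIS window clipped by the frame edge; using the truncated window.")
    r0 <- max(r0, 1L); c0 <- max(c0, 1L)
    r1 <- min(r1, nrow(frame)); c1 <- min(c1, ncol(frame))
  }
  vals <- sort(frame[r0:r1, c0:c1], decreasing = TRUE)
  mean(vals[seq_len(min(n_top, length(vals)))])
}

#' Running-minimum baseline dF/F
#'
#' Smooths the raw trace with a centered moving average over `smooth_s`
#' seconds, then computes `F0(t) = min of F over [0, t]` (the running
#' minimum) and `dFF = (F - F0) / F0`. The running-minimum baseline makes
#' `dFF` non-negative by construction and insensitive to slow additive
#' drifts in absolute brightness only through its ratio form; it requires a
#' strictly positive baseline.
#'
#' @param F Numeric vector of raw fluorescence (a.u.).
#' @param fps Frames per second (needed when `smooth_s > 0`).
#' @param smooth_s Smoothing window in seconds (default 3; use 0 for none).
#' @return An object of class `fluor_trace`: a tibble with columns
#'   `time_s`, `F` (smoothed), `F0`, `dFF`.
#' @export
#' @examples
#' delta_f_over_f(c(5, 4, 6), fps = 1, smooth_s = 0)$dFF  # 0, 0, 0.5
delta_f_over_f <- function(F, fps = NULL, smooth_s = 3) {
  if (length(F) == 0L) abort("`F` must be non-empty.")
  check_number(smooth_s, "smooth_s", min = 0)
  if (smooth_s > 0) {
    if (is.null(fps)) abort("`fps` is required when `smooth_s > 0`.")
    F <- moving_average(F, window_frames(smooth_s, fps))
  }
  F0 <- cummin(F)
  if (any(F0 <= 0)) {
    abort("Degenerate baseline: running-minimum fluorescence is not positive.")
  }
  out <- tibble(
    time_s = if (is.null(fps)) seq_along(F) - 1
             else (seq_along(F) - 1) / fps,
    F = F,
    F0 = F0,
    dFF = (F - F0) / F0
  )
  class(out) <- c("fluor_trace", class(out))
  out
}

#' Ratiometric dR/R from two-channel dF/F traces
#'
#' `R(t) = dFF_gcamp(t) / max(dFF_mkate(t), denom_floor)`; the floor guards
#' the denominator, which is exactly 0 wherever the mKate trace touches its
#' running minimum. `R0` is the lower 20th-percentile value of `R` (linear
#' interpolation between order statistics) and `dRR = (R - R0) / R0`.
#' Because GCaMP reports calcium while mKate does not, the ratio cancels
#' motion and bleaching common to both channels.
#'
#' @param gcamp,mkate `fluor_trace` objects from [delta_f_over_f()] (aligned
#'   time bases), or plain numeric dF/F vectors.
#' @param denom_floor Lower clamp on the mKate dF/F (default 0.01).
#' @param baseline_percentile Percentile of `R` used as `R0` (default 20).
#' @return An object of class `ratio_trace`: a tibble with columns `time_s`,
#'   `R`, `dRR`, and attribute `R0`.
#' @export
delta_r_over_r <- function(gcamp, mkate, denom_floor = 0.01,
                           baseline_percentile = 20) {
  gd <- if (is.data.frame(gcamp)) gcamp$dFF else gcamp
  md <- if (is.data.frame(mkate)) mkate$dFF else mkate
  ts <- if (is.data.frame(gcamp)) gcamp$time_s else seq_along(gd) - 1
  if (length(gd) != length(md)) {
    abort("GCaMP and mKate traces must be aligned (equal length).")
  }
  check_number(denom_floor, "denom_floor", min = 0, strict = TRUE)
  if (all(md <= 0)) {
    abort("Degenerate denominator: mKate dF/F is never positive.")
  }
  R <- gd / pmax(md, denom_floor)
  R0 <- percentile(R, baseline_percentile)
  if (R0 == 0) abort("Degenerate baseline: R0 is zero.")
  out <- tibble(time_s = ts, R = R, dRR = (R - R0) / R0)
  attr(out, "R0") <- R0
  class(out) <- c("ratio_trace", class(out))
  out
}

#' Behavior metric from tracked neuron positions
#'
#' Per frame pair, the mean Euclidean displacement of the tracked neurons,
#' then smoothed and normalized exactly like a frame-subtraction activity
#' trace ([normalize_activity()]).
#'
#' @param positions Numeric array `[n_neurons, 2, n_frames]` of `(row, col)`
#'   positions, or a list of per-frame `n_neurons x 2` matrices. Neurons
#'   with missing (NA) positions in a frame pair are excluded from that
#'   pair's mean with a warning.
#' @param fps Frames per second.
#' @param smoothing_window_s,norm_percentile Passed to
#'   [normalize_activity()]; use `smoothing_window_s = 0` to skip smoothing.
#' @return A tibble with columns `frame`, `time_s`, `raw` (px/frame pair),
#'   `normalized`.
#' @export
displacement_behavior <- function(positions, fps, smoothing_window_s = 3,
                                  norm_percentile = 95) {
  if (is.list(positions)) {
    positions <- simplify2array(positions)  # n x 2 x frames
  }
  d <- dim(positions)
  if (length(d) != 3L || d[2L] != 2L) {
    abort("`positions` must be [n_neurons, 2, n_frames].")
  }
  if (d[3L] < 2L) abort("Need at least 2 frames of positions.")
  disp <- sqrt((positions[, 1L, -1L, drop = FALSE] -
                  positions[, 1L, -d[3L], drop = FALSE])^2 +
               (positions[, 2L, -1L, drop = FALSE] -
                  positions[, 2L, -d[3L], drop = FALSE])^2)
  disp <- matrix(disp, nrow = d[1L])  # neurons x frame pairs
  if (anyNA(disp)) {
    warn("Missing neuron positions; affected neurons excluded per frame pair.")
  }
  raw <- colMeans(disp, na.rm = TRUE)
  if (anyNA(raw)) abort("Some frame pairs have no tracked neurons at all.")
  tibble(
    frame = seq_along(raw) - 1L,
    time_s = (seq_along(raw) - 1L) / fps,
    raw = raw,
    normalized = normalize_activity(raw, fps, smoothing_window_s,
                                    norm_percentile)
  )
}

#' Mean fluorescence during wake and sleep
#'
#' Averages a dF/F or dR/R series separately over frames inside and outside
#' the sleep bouts.
#'
#' @param x Numeric series, or a `fluor_trace` / `ratio_trace` (uses `dFF` /
#'   `dRR`).
#' @param bouts A `bout_set` from [detect_bouts()] (or any data frame with
#'   `start_s`, `end_s`).
#' @param fps Frames per second of the series.
#' @return A one-row tibble with `wake_mean`, `sleep_mean`, `n_wake`,
#'   `n_sleep`; a state with no frames yields `NA`.
#' @export
state_fluorescence_summary <- function(x, bouts, fps) {
  series <- if (is.data.frame(x)) {
    if ("dRR" %in% names(x)) x$dRR else x$dFF
  } else {
    x
  }
  time_s <- (seq_along(series) - 1) / fps
  asleep <- rep(FALSE, length(series))
  for (i in seq_len(nrow(bouts))) {
    asleep <- asleep |
      (time_s >= bouts$start_s[i] & time_s < bouts$end_s[i])
  }
  tibble(
    wake_mean = if (any(!asleep)) mean(series[!asleep]) else NA_real_,
    sleep_mean = if (any(asleep)) mean(series[asleep]) else NA_real_,
    n_wake = sum(!asleep),
    n_sleep = sum(asleep)
  )
}

#' Windowed behavior-fluorescence correlation with shuffle control
#'
#' Splits both series into consecutive non-overlapping windows of
#' `window_s` seconds and computes the Pearson correlation within each
#' window. As a control, the pairing of fluorescence windows to behavior
#' windows is permuted uniformly at random `n_shuffles` times and the
#' per-window correlations recomputed; a genuine behavior-fluorescence
#' relationship survives only in the unshuffled pairing. The identity
#' permutation is allowed by default (a derangement is not enforced), which
#' leaves a small residual of the true correlation, about `mean(r) / K` for
#' `K` windows, in the shuffled distribution.
#'
#' @param behavior,fluor Aligned numeric series (equal length).
#' @param fps Samples per second.
#' @param window_s Window length in seconds (default 600, i.e. 10 min).
#' @param n_shuffles Number of random window permutations (default 5000).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param exclude_identity If `TRUE`, resample any permutation that turns
#'   out to be the identity.
#' @return A list with `window_r` (tibble: `window`, `r`) and `shuffled`
#'   (tibble: `shuffle`, `window`, `r`). Windows where either series is
#'   constant are skipped with a warning.
#' @export
windowed_correlation <- function(behavior, fluor, fps, window_s = 600,
                                 n_shuffles = 5000, seed = NULL,
                                 exclude_identity = FALSE) {
  if (length(behavior) != length(fluor)) {
    abort("`behavior` and `fluor` must be aligned (equal length).")
  }
  wlen <- window_frames(window_s, fps)
  k <- length(behavior) %/% wlen
  if (k < 2L) abort("Need at least 2 full windows for the shuffle control.")
  idx <- function(i) ((i - 1L) * wlen + 1L):(i * wlen)
  bw <- purrr::map(seq_len(k), function(i) behavior[idx(i)])
  fw <- purrr::map(seq_len(k), function(i) fluor[idx(i)])
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  r <- purrr::map2_dbl(bw, fw, safe_cor)
  if (anyNA(r)) warn("Constant series in some window(s); those are skipped.")
  window_r <- tibble(window = seq_len(k), r = r)
  shuffled <- with_seed_or_not(seed, {
    purrr::map_dfr(seq_len(n_shuffles), function(s) {
      perm <- sample.int(k)
      if (exclude_identity) {
        while (all(perm == seq_len(k))) perm <- sample.int(k)
      }
      tibble(shuffle = s, window = seq_len(k),
             r = purrr::map2_dbl(bw, fw[perm], safe_cor))
    })
  })
  list(window_r = dplyr::filter(window_r, !is.na(.data$r)),
       shuffled = dplyr::filter(shuffled, !is.na(.data$r)))
}
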