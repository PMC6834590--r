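# Synthetic puncta images with exact pixel-area ground truth.

#' Render a synthetic puncta image
#'
#' Draws a dim worm-body ellipse on a darker background and places
#' `n_puncta` bright, compact, non-touching blobs inside it, each with a
#' pixel area drawn uniformly from `area_range_px`. A blob of area `a` is
#' the set of the `a` grid pixels nearest its center, so the ground-truth
#' area is exact. `distractor_areas` adds out-of-range blobs (for example
#' 1 px and 40 px) that appear in the image but are deliberately excluded
#' from the returned truth table — a negative-control fixture for the
#' size gate.
#'
#' @param shape_px Image size `(height, width)` in pixels.
#' @param n_puncta Number of in-range puncta.
#' @param area_range_px Inclusive area range `(min, max)` in pixels
#'   (default `c(2, 30)`, the reported size gate).
#' @param background_level Grey level outside the body (default 10).
#' @param body_level Grey level of the body ellipse (default 40).
#' @param puncta_level Grey level of puncta pixels (default 200).
#' @param distractor_areas Optional vector of out-of-range blob areas to
#'   render but exclude from truth.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with `image` (numeric matrix), `background` (constant
#'   matrix at `background_level`, as captured after flushing animals), and
#'   `truth` (tibble: `id`, `row`, `col` centroid, `area_px`).
#' @export
#' @examples
#' out <- render_puncta_image(c(96, 96), n_puncta = 5, seed = 1)
#' out$truth
render_puncta_image <- function(shape_px = c(128L, 128L), n_puncta = 10L,
                                area_range_px = c(2L, 30L),
                                background_level = 10, body_level = 40,
                                puncta_level = 200,
                                distractor_areas = NULL, seed = NULL) {
  h <- shape_px[1L]; w <- shape_px[2L]
  if (n_puncta < 0L) abort("`n_puncta` must be >= 0.")
  if (area_range_px[1L] < 1L || area_range_px[2L] < area_range_px[1L]) {
    abort("`area_range_px` must be an increasing range of positive areas.")
  }
  with_seed_or_not(seed, {
    img <- matrix(background_level, h, w)
    # body ellipse, centered, elongated along the wider axis
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ay <- 0.28 * h; ax <- 0.42 * w
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    in_body <- ((rows - cy) / ay)^2 + ((cols - cx) / ax)^2 <= 1
    img[in_body] <- body_level

    areas <- c(
      if (n_puncta > 0L)
        sample(seq(area_range_px[1L], area_range_px[2L]), n_puncta,
               replace = TRUE),
      distractor_areas
    )
    n_total <- length(areas)
    truth <- tibble(id = integer(), row = numeric(), col = numeric(),
                    area_px = numeric())
    if (n_total > 0L) {
      max_r <- ceiling(sqrt(max(areas) / pi)) + 1
      min_sep <- 2 * max_r + 3  # centers far enough apart never to touch
      margin <- max_r + 2
      centers <- matrix(numeric(), 0L, 2L)
      tries <- 0L
      while (nrow(centers) < n_total) {
        tries <- tries + 1L
        if (tries > 20000L) {
          abort("Infeasible packing: cannot place puncta without touching.")
        }
        cand <- c(runif(1, 1 + margin, h - margin),
                  runif(1, 1 + margin, w - margin))
        inside <- ((cand[1L] - cy) / (ay - margin))^2 +
          ((cand[2L] - cx) / (ax - margin))^2 <= 1
        if (!inside) next
        if (nrow(centers) > 0L &&
            min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) < min_sep) next
        centers <- rbind(centers, cand)
      }
      for (i in seq_len(n_total)) {
        a <- areas[i]
        rr <- round(centers[i, 1L]); cc <- round(centers[i, 2L])
        nb_r <- max(1L, rr - max_r - 2L):min(h, rr + max_r + 2L)
        nb_c <- max(1L, cc - max_r - 2L):min(w, cc + max_r + 2L)
        grid <- expand.grid(r = nb_r, c = nb_c)
        d2 <- (grid$r - centers[i, 1L])^2 + (grid$c - centers[i, 2L])^2
        pick <- order(d2)[seq_len(a)]  # a nearest pixels: compact & connected
        px <- grid[pick, ]
        img[cbind(px$r, px$c)] <- puncta_level
        if (a >= area_range_px[1L] && a <= area_range_px[2L]) {
          truth <- dplyr::bind_rows(truth, tibble(
            id = i, row = mean(px$r), col = mean(px$c), area_px = a
          ))
        }
      }
    }
    list(
      image = img,
      background = matrix(background_level, h, w),
      truth = truth
    )
  })
}
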