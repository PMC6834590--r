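# Reading video stacks and writing tidy results.

#' Read a grayscale video stack
#'
#' Accepts a multi-page TIFF or a directory of image frames (`.tif`,
#' `.tiff`, `.png`) ordered by file name. Pixel values are returned as
#' integers at the recorded bit depth (PNG is assumed 8-bit; TIFF uses its
#' `bits.per.sample`). Multi-channel frames are reduced to their first
#' channel.
#'
#' @param path Path to a TIFF file or a directory of frames.
#' @return Integer array `[height, width, frames]` with attribute
#'   `bits_per_sample`.
#' @export
read_video <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file or directory: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) abort("Directory contains no image frames.")
    frames <- purrr::map(files, read_frame)
    bits <- attr(frames[[1L]], "bits_per_sample") %||% 8L
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1L]], "bits.per.sample") %||% 8L
    frames <- purrr::map(pages, drop_channels)
  }
  dims <- purrr::map(frames, dim)
  if (length(unique(purrr::map_chr(dims, paste, collapse = "x"))) > 1L) {
    abort("Frames have mixed shapes.")
  }
  video <- array(
    as.integer(round(unlist(frames))),
    c(dim(frames[[1L]]), length(frames))
  )
  attr(video, "bits_per_sample") <- bits
  video
}

read_frame <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext == "png") {
    img <- drop_channels(png::readPNG(f))
    out <- round(img * 255)
    attr(out, "bits_per_sample") <- 8L
    out
  } else {
    img <- tiff::readTIFF(f, as.is = TRUE)
    out <- drop_channels(img)
    attr(out, "bits_per_sample") <- attr(img, "bits.per.sample") %||% 8L
    out
  }
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img[, , 1L] else img
}

#' Write a video stack as a multi-page TIFF
#'
#' @param video Integer array `[height, width, frames]`.
#' @param path Output file path.
#' @param bits_per_sample Bit depth (8 or 16).
#' @return The path, invisibly.
#' @export
write_video <- function(video, path, bits_per_sample = 8L) {
  maxval <- 2^bits_per_sample - 1
  pages <- purrr::map(seq_len(dim(video)[3L]), function(i) {
    video[, , i] / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Write tidy result tables and a run manifest
#'
#' Writes `traces.csv` (one row per frame pair per animal), `bouts.csv`
#' (one row per bout), `stats.csv` (one row per animal, scalar statistics),
#' and `manifest.json` capturing the configuration, seeds, and package
#' version. Reruns with identical inputs produce byte-identical files.
#'
#' @param traces A tibble from [activity_trace()] (or several row-bound).
#' @param bouts A `bout_set` or list of them.
#' @param stats A tibble from [bout_statistics()] (or several row-bound);
#'   list-columns are dropped from the CSV.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration list stored in the manifest.
#' @return The directory, invisibly.
#' @export
write_results <- function(traces = NULL, bouts = NULL, stats = NULL,
                          dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(traces)) {
    readr::write_csv(traces, file.path(dir, "traces.csv"))
  }
  if (!is.null(bouts)) {
    if (inherits(bouts, "bout_set")) bouts <- list(bouts)
    readr::write_csv(purrr::map_dfr(bouts, tidy), file.path(dir, "bouts.csv"))
  }
  if (!is.null(stats)) {
    scalar <- stats[!purrr::map_lgl(stats, is.list)]
    readr::write_csv(scalar, file.path(dir, "stats.csv"))
  }
  manifest <- list(
    package = "wormstate",
    version = as.character(utils::packageVersion("wormstate")),
    config = config
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
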