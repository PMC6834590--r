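# Internal numeric helpers shared across modules.

#' Centered moving average with edge truncation
#'
#' Smooths a series with a centered boxcar. The window is truncated at the
#' series edges, so the first and last values average over fewer points
#' rather than being dropped or padded.
#'
#' @param x Numeric vector.
#' @param window Integer window length in samples. `window <= 1` returns `x`
#'   unchanged.
#' @return Numeric vector, same length as `x`.
#' @keywords internal
#' @noRd
moving_average <- function(x, window) {
  n <- length(x)
  window <- as.integer(window)
  if (window <= 1L || n == 0L) return(x)
  # centered window: `left` samples before, `right` after (left <= right)
  left <- (window - 1L) %/% 2L
  right <- window - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Convert a window in seconds to a window in frames
#' @noRd
window_frames <- function(window_s, fps) {
  as.integer(round(window_s * fps))
}

#' Percentile with linear interpolation between order statistics
#'
#' Thin wrapper fixing the quantile convention used everywhere in the
#' package (type 7, R's default linear interpolation).
#' @noRd
percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' `seed = NULL` leaves the RNG stream alone (caller-controlled randomness).
#' @noRd
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Validate a scalar
#' @noRd
check_number <- function(x, name, min = -Inf, strict = FALSE, finite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  invisible(x)
}

#' Run-length encode a logical vector into a start/end tibble
#'
#' Returns half-open index intervals (1-based start, exclusive end) for
#' maximal `TRUE` runs.
#' @noRd
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep] + 1L)
}

#' 8-connected component labeling of a binary matrix
#'
#' Uses an igraph over foreground pixels; suited to the sparse masks
#' produced by puncta detection and skeletonization.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels (0 = background).
#' @noRd
label_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- match(idx, idx)  # 1..k
  lookup <- integer(length(mask))
  lookup[idx] <- pos
  # neighbor offsets for 8-connectivity in column-major indexing
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1L]; c2 <- cc + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[nb] > 0L
    edges[[length(edges) + 1L]] <- rbind(pos[ok][hit], lookup[nb][hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && ncol(em) > 0L) g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' 3x3 neighborhood median filter
#'
#' Median over the 3x3 neighborhood of each pixel; edges use replicated
#' borders. Vectorized via a shifted-stack sort.
#' @noRd
median_filter_3x3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  padded <- img[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  stack <- vapply(
    seq_len(9L),
    function(k) {
      dr <- (k - 1L) %% 3L
      dc <- (k - 1L) %/% 3L
      as.vector(padded[dr + seq_len(nr), dc + seq_len(nc)])
    },
    numeric(nr * nc)
  )
  matrix(apply(stack, 1L, median), nr, nc)
}

#' 3x3 linear filter (direct convolution, replicated borders)
#' @noRd
filter_3x3 <- function(img, kernel) {
  stopifnot(all(dim(kernel) == c(3L, 3L)))
  nr <- nrow(img); nc <- ncol(img)
  padded <- img[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) {
    for (dc in 0:2) {
      out <- out + kernel[dr + 1L, dc + 1L] *
        padded[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  out
}

#' Gaussian smoothing of a 1-D sequence, edge-renormalized
#' @noRd
smooth_1d_gaussian <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  xp <- c(rep(0, r), x, rep(0, r))
  wp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- numeric(n); den <- numeric(n)
  for (j in seq_along(k)) {
    num <- num + k[j] * xp[(j - 1L) + seq_len(n)]
    den <- den + k[j] * wp[(j - 1L) + seq_len(n)]
  }
  num / den
}

#' Separable Gaussian blur with reflected borders
#' @noRd
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {
    n <- nrow(m)
    pad_idx <- c(rev(seq_len(r)), seq_len(n), n - seq_len(r) + 1L)
    mp <- m[pad_idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}
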