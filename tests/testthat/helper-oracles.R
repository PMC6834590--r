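# Independent brute-force oracles used by the unit and acceptance tests.

# Bout detection by direct run enumeration: find maximal below-threshold
# runs from the index list, merge across short gaps with an explicit loop,
# then apply the minimum-duration filter. Deliberately written with a
# different mechanism than the package implementation (index diffs + a
# scalar merge loop instead of rle/grouped indexing).
oracle_bouts <- function(normalized, fps, threshold,
                         min_bout_s = 30, max_twitch_s = 15) {
  below <- normalized < threshold
  idx <- which(below)
  if (length(idx) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  new_run <- c(TRUE, diff(idx) != 1L)
  starts <- idx[new_run]
  ends <- idx[c(new_run[-1L], TRUE)] + 1L  # exclusive end index
  K <- length(starts)
  out_s <- numeric(K); out_e <- numeric(K)
  m <- 1L
  out_s[1L] <- starts[1L]; out_e[1L] <- ends[1L]
  if (K > 1L) {
    for (k in 2:K) {
      if ((starts[k] - out_e[m]) / fps < max_twitch_s) {
        out_e[m] <- ends[k]
      } else {
        m <- m + 1L
        out_s[m] <- starts[k]; out_e[m] <- ends[k]
      }
    }
  }
  out_s <- out_s[seq_len(m)]; out_e <- out_e[seq_len(m)]
  keep <- (out_e - out_s) / fps >= min_bout_s
  tibble::tibble(
    start_s = (out_s[keep] - 1) / fps,
    end_s = (out_e[keep] - 1) / fps
  )
}

# Type-7 percentile by the textbook order-statistic interpolation formula.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# Alternating wake/sleep schedule with uniformly distributed bout lengths;
# used where every analysis window must straddle a state transition.
uniform_schedule <- function(duration_s, range_s = c(200, 400), seed = 1) {
  withr::with_seed(seed, {
    t0 <- 0; starts <- numeric(); ends <- numeric(); state_sleep <- FALSE
    repeat {
      len <- runif(1, range_s[1], range_s[2])
      t1 <- min(t0 + len, duration_s)
      if (state_sleep) {
        starts <- c(starts, t0); ends <- c(ends, t1)
      }
      state_sleep <- !state_sleep
      t0 <- t1
      if (t0 >= duration_s) break
    }
    bout_schedule(data.frame(start_s = starts, end_s = ends),
                  duration_s = duration_s)
  })
}
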