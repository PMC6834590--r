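# Stimulus-response quantification: pre-state classification, post-stimulus
# response, fraction awake with bootstrap, and permutation significance.

#' Classify the behavioral state before a stimulus
#'
#' Mean normalized activity over the `pre_window_s` seconds before the
#' stimulus, mapped to `"sleep"` (< 0.08), `"low_wake"` ([0.08, 0.35],
#' boundaries inclusive), or `"high_wake"` (> 0.35). The two wake classes
#' matter because animals already moving at high activity cannot show a
#' detectable response increase. Use unsmoothed activity at these fine
#' timescales.
#'
#' @param normalized Numeric activity series (one value per frame pair;
#'   index `i` covers `[(i-1)/fps, i/fps)`).
#' @param stim_time_s Stimulus time in seconds.
#' @param fps Frames per second.
#' @param pre_window_s Pre-stimulus window length (default 10 s).
#' @param sleep_threshold,high_threshold Class boundaries (defaults 0.08 and
#'   0.35).
#' @return A list with `state` (label) and `pre_mean`.
#' @export
classify_pre_state <- function(normalized, stim_time_s, fps,
                               pre_window_s = 10,
                               sleep_threshold = 0.08,
                               high_threshold = 0.35) {
  i1 <- floor(stim_time_s * fps)             # frames strictly before stimulus
  i0 <- i1 - window_frames(pre_window_s, fps) + 1L
  if (i0 < 1L || i1 > length(normalized) || i1 < i0) {
    abort("Pre-stimulus window is outside the recording; trial excluded.")
  }
  pre_mean <- mean(normalized[i0:i1])
  state <- if (pre_mean < sleep_threshold) {
    "sleep"
  } else if (pre_mean > high_threshold) {
    "high_wake"
  } else {
    "low_wake"
  }
  list(state = state, pre_mean = pre_mean)
}

#' Mean post-stimulus response excluding the valve artifact
#'
#' Mean normalized activity over `(stim_time + artifact_s,
#' stim_time + post_window_s]`: the first `artifact_s` seconds after the
#' stimulus are excluded because pressurizing the valves itself displaces
#' the animal and inflates apparent activity.
#'
#' @inheritParams classify_pre_state
#' @param post_window_s Post-stimulus window length (default 10 s).
#' @param artifact_s Artifact exclusion at the start of the window
#'   (default 2 s; use 0 for light stimuli, which move nothing).
#' @return The post-stimulus mean activity.
#' @export
post_response <- function(normalized, stim_time_s, fps,
                          post_window_s = 10, artifact_s = 2) {
  if (artifact_s >= post_window_s) {
    abort("`artifact_s` must be smaller than `post_window_s`.")
  }
  i0 <- floor((stim_time_s + artifact_s) * fps) + 1L
  i1 <- floor(stim_time_s * fps) + window_frames(post_window_s, fps)
  if (i0 < 1L || i1 > length(normalized) || i1 < i0) {
    abort("Post-stimulus window is outside the recording; trial excluded.")
  }
  mean(normalized[i0:i1])
}

#' Build a tidy trial table for a stimulation protocol
#'
#' Applies [classify_pre_state()] and [post_response()] at every stimulus
#' time; trials whose windows fall outside the recording are dropped.
#'
#' @inheritParams classify_pre_state
#' @inheritParams post_response
#' @param stim_times_s Numeric vector of stimulus times.
#' @param stim_kind Label stored with each trial (e.g. `"mech_weak"`).
#' @param animal_id Identifier.
#' @return A tibble with one row per usable trial: `animal_id`,
#'   `stim_time_s`, `stim_kind`, `pre_state`, `pre_mean`, `post_mean`.
#' @export
stimulus_trials <- function(normalized, stim_times_s, fps,
                            stim_kind = "mech_weak", animal_id = "animal1",
                            pre_window_s = 10, post_window_s = 10,
                            artifact_s = 2,
                            sleep_threshold = 0.08, high_threshold = 0.35) {
  purrr::map_dfr(stim_times_s, function(t0) {
    res <- tryCatch({
      pre <- classify_pre_state(normalized, t0, fps, pre_window_s,
                                sleep_threshold, high_threshold)
      post <- post_response(normalized, t0, fps, post_window_s, artifact_s)
      tibble(animal_id = animal_id, stim_time_s = t0, stim_kind = stim_kind,
             pre_state = pre$state, pre_mean = pre$pre_mean,
             post_mean = post)
    }, error = function(e) NULL)
    res
  })
}

#' Fraction of trials awake after the stimulus, with bootstrap SD
#'
#' A trial counts as awake when its post-stimulus mean activity exceeds
#' `wake_threshold` (by default the sleep-detection threshold of the
#' geometry in use). The standard deviation comes from resampling the
#' trials with replacement `n_boot` times.
#'
#' @param post_means Numeric vector of per-trial post-stimulus means, or a
#'   trial tibble from [stimulus_trials()] (uses `post_mean`).
#' @param wake_threshold Activity above which a trial counts as awake.
#' @param n_boot Bootstrap iterations (default 5000).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A one-row tibble: `fraction`, `bootstrap_sd`, `n_trials`.
#' @export
fraction_awake <- function(post_means, wake_threshold = 0.06,
                           n_boot = 5000L, seed = NULL) {
  if (is.data.frame(post_means)) post_means <- post_means$post_mean
  n <- length(post_means)
  if (n < 1L) abort("Need at least one trial.")
  if (n_boot < 1L) abort("`n_boot` must be >= 1.")
  awake <- post_means > wake_threshold
  boot_sd <- with_seed_or_not(seed, {
    draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    fracs <- colMeans(matrix(awake[draws], nrow = n))
    sd(fracs) * sqrt((n_boot - 1) / n_boot)  # population SD of the resamples
  })
  tibble(fraction = mean(awake), bootstrap_sd = boot_sd, n_trials = n)
}

#' Permutation test on the difference of two group fractions
#'
#' Pools the binary outcomes of both groups, reassigns group labels
#' uniformly at random preserving the group sizes, and compares the
#' observed difference in fractions against `n_iter` permuted differences.
#' Two-sided Monte-Carlo p-value with the add-one correction,
#' `p = (1 + #{|d*| >= |d_obs|}) / (1 + n_iter)`, then Bonferroni-adjusted
#' by `n_comparisons` and capped at 1.
#'
#' For binary outcomes, uniformly relabeling the pooled vector makes the
#' group-A success count exactly hypergeometric, which is how the permuted
#' differences are drawn (identical in distribution to explicit label
#' shuffling, and much faster).
#'
#' @param group_a,group_b Logical or 0/1 outcome vectors.
#' @param n_iter Permutation iterations (default 5000).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A one-row tibble: `diff_obs`, `p_raw`, `p_adjusted`.
#' @export
resampling_test <- function(group_a, group_b, n_iter = 5000L,
                            n_comparisons = 1L, seed = NULL) {
  a <- as.integer(as.logical(group_a))
  b <- as.integer(as.logical(group_b))
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both groups must be non-empty.")
  }
  if (anyNA(a) || anyNA(b)) abort("Outcomes must not contain NA.")
  na <- length(a); nb <- length(b)
  k <- sum(a) + sum(b)
  d_obs <- mean(a) - mean(b)
  p_raw <- with_seed_or_not(seed, {
    ka <- rhyper(n_iter, k, na + nb - k, na)
    d_star <- ka / na - (k - ka) / nb
    (1 + sum(abs(d_star) >= abs(d_obs) - 1e-12)) / (1 + n_iter)
  })
  tibble(
    diff_obs = d_obs,
    p_raw = p_raw,
    p_adjusted = min(1, p_raw * n_comparisons)
  )
}
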