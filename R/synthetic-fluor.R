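# Synthetic fluorescence traces with known state contrast and bleaching.

#' Simulate state-dependent fluorescence traces
#'
#' Ordinary neurons emit a high mean signal during wake and a reduced mean
#' during sleep (most neural activity falls in the quiescent state). With
#' `ris_like = TRUE`, channel `"neuron1"` instead follows the opposite,
#' sleep-active pattern of the RIS interneuron, rising by `ris_gain` during
#' sleep. All channels are multiplied by a shared photobleaching factor
#' `exp(-t / bleach_tau_s)`, and a state-independent `"red"` reference
#' channel (an mKate-like fluorophore) with the same bleach factor is always
#' included. Gaussian noise of standard deviation `noise_sd` is added after
#' bleaching.
#'
#' @param schedule A [bout_schedule()].
#' @param n_neurons Number of green channels (default 10, the number of
#'   hand-tracked neurons in whole-brain recordings).
#' @param fps Samples per second (default 5 for whole-brain, use 0.5 for
#'   two-color RIS imaging).
#' @param bleach_tau_s Photobleaching time constant in seconds (`Inf` for
#'   none).
#' @param ris_like Make channel 1 sleep-active.
#' @param noise_sd Additive noise (a.u.).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param wake_level Noiseless wake-state signal of an ordinary neuron.
#' @param sleep_wake_ratio Ordinary-neuron sleep/wake mean ratio
#'   (default 0.4).
#' @param ris_gain RIS-like sleep/wake mean ratio (default 2).
#' @param red_level Constant level of the red reference channel.
#' @return A list with `traces` (tibble: `channel`, `frame`, `time_s`, `F`)
#'   and `truth` (tibble of the noiseless signals in the same layout, plus
#'   the per-frame `asleep` flag and the bleach factor).
#' @export
simulate_fluorescence <- function(schedule, n_neurons = 10L, fps = 5,
                                  bleach_tau_s = Inf, ris_like = FALSE,
                                  noise_sd = 0.02, seed = NULL,
                                  wake_level = 1, sleep_wake_ratio = 0.4,
                                  ris_gain = 2, red_level = 1) {
  if (n_neurons < 1L) abort("`n_neurons` must be >= 1.")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(bleach_tau_s, "bleach_tau_s", min = 0, strict = TRUE)
  st <- schedule_state(schedule, fps)
  n <- nrow(st)
  bleach <- exp(-st$time_s / bleach_tau_s)
  state_level <- ifelse(st$asleep, sleep_wake_ratio * wake_level, wake_level)
  ris_level <- ifelse(st$asleep, ris_gain * wake_level, wake_level)
  channels <- c(paste0("neuron", seq_len(n_neurons)), "red")
  signal <- purrr::map(seq_along(channels), function(i) {
    if (channels[i] == "red") {
      red_level * bleach
    } else if (ris_like && i == 1L) {
      ris_level * bleach
    } else {
      state_level * bleach
    }
  })
  truth <- purrr::map2_dfr(channels, signal, function(ch, s) {
    tibble(channel = ch, frame = st$frame, time_s = st$time_s,
           F = s, asleep = st$asleep, bleach = bleach)
  })
  traces <- with_seed_or_not(seed, {
    purrr::map2_dfr(channels, signal, function(ch, s) {
      tibble(channel = ch, frame = st$frame, time_s = st$time_s,
             F = s + if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0)
    })
  })
  list(traces = traces, truth = truth)
}
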