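---
title: "Quantifying microfluidic-induced sleep: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microfluidic-induced sleep: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormstate)
```

Worms confined in microfluidic chambers spontaneously enter a reversible
quiescent state with the behavioral signatures of sleep: bouts of immobility
lasting minutes, a stereotyped bent posture, reduced responsiveness to
stimuli, and sleep-active neuron signaling. This vignette describes, stage
by stage, how `wormstate` quantifies each signature, why each parameter has
the value it has, and which numerical conventions the implementation pins
down. The companion synthetic generators are described alongside the
analyses they validate.

## Activity from video

Movement is quantified by frame-by-frame subtraction
(`frame_difference_activity()`): for each consecutive frame pair, the number
of pixels inside the animal's region of interest whose grey value changes by
**strictly more than 30 grey levels**. The threshold separates genuine
movement from sensor noise on 8-bit behavioral video; the two-color
sleep-neuron imaging configuration records on a 16-bit sensor and uses 400
instead (`experiment_config("ris_50um")`). Differences are computed on
widened (double) values so unsigned 8-bit input cannot wrap around.

The raw count series is smoothed with a **centered 20-s moving average**
(window truncated at the recording edges, so early and late frames average
over what exists) and divided by the **95th percentile** of the smoothed
series (`normalize_activity()`). Percentiles here and everywhere else in the
package use linear interpolation between order statistics (R's quantile
type 7). Normalized activity is approximately in `[0, 1]`; the top tail may
exceed 1 and is deliberately not clipped, so the normalization is a scale,
not a censoring.

Two conventions matter downstream: series index `i` covers the time interval
`[(i-1)/fps, i/fps)` (half-open, frame-pair resolution), and a full-frame
region of interest is the default when none is given.

## Sleep bouts

`detect_bouts()` classifies a frame as candidate-quiescent when its
normalized activity is **strictly below** the geometry threshold:

| geometry | threshold |
|---|---|
| WorMotel well | 0.15 |
| 500-µm chamber | 0.15 |
| 110-µm chamber | 0.08 |
| 50-µm chamber | 0.06 |
| 50-µm chamber, two-color sleep-neuron imaging | 0.20 |

Tighter chambers constrain residual wake movement more, so their thresholds
are stricter. Candidate runs are then post-processed in a fixed order:

1. **Merge** runs separated by supra-threshold gaps strictly shorter than
   15 s (`max_twitch_s`): sleeping animals twitch briefly without waking.
2. **Discard** merged runs shorter than 30 s (`min_bout_s`): sub-30-s
   quiescence is not scored as sleep.

Merging precedes the minimum-duration filter so that a long bout interrupted
by a single twitch survives as a unit; two 20-s half-bouts joined by a 10-s
twitch form one 50-s bout rather than being discarded piecemeal. A bout
truncated by the end of the recording is kept if its observed length reaches
30 s. Bout intervals are half-open `[start_s, end_s)` at frame resolution.

`bout_statistics()` derives the per-animal quantities used in group
comparisons. Wake-bout lengths are the gaps between consecutive sleep bouts
plus the terminal gap; the wake period before the first bout is excluded
because its onset was not observed. Homeostasis pairs match each sleep bout
with the length of the wake bout immediately preceding it; the first bout
has no observed preceding wake bout and is excluded. For a 3600-s recording
with bouts `[100, 160)` and `[400, 490)` this yields wake bouts
`240, 3110` and the single pair `(240, 90)`.

`bout_sensitivity()` reruns detection over `min_bout_s` in `{15, 30, 60}`,
the robustness check that headline comparisons should survive.

### What the 20-s smoother does to bout boundaries

Smoothing leaks wake activity into the edges of each sleep bout: with wake
activity near 1.0 and a threshold of 0.15, the smoothed trace falls below
threshold only once the 20-s window overlaps wake by less than about 3 s,
so each boundary moves inward by roughly 7–9 s and each detected bout is
some 14–17 s shorter than its generating interval. This is a property of
the estimator, not an error; the acceptance tests therefore check **pooled**
total sleep against truth (the quantity group comparisons consume), require
boundary accuracy of one smoothing window only for bouts long enough to
survive smoothing with margin, and accept that a twitch occurring within a
few seconds of a bout edge legitimately delays the measurable onset.

## Posture

`extract_centerline()` reduces a frame to an ordered body centerline:
background subtraction, contrast stretch, Otsu binarization, retention of
the largest connected object, Gaussian smoothing of the mask
(`sigma = 1` px), Zhang–Suen thinning to a 1-px skeleton, and the longest
geodesic path through the skeleton graph (8-connected, Euclidean edge
weights, double-sweep). Side branches of the skeleton drop out implicitly
because they never lie on the maximal geodesic.

The thinned path carries lattice stair-stepping whose wavelength grows
without bound where the body runs nearly parallel to a pixel axis, so no
fixed-width filter can remove it without also destroying genuine curvature.
The path is therefore regularized by an **unconstrained least-squares
polynomial fit** (degree 8, orthogonal basis in arclength) of row and column
against arclength. Degree 8 resolves bends down to about a quarter body
length — ample for crawling postures — while rejecting pixel-scale
aliasing; an unconstrained fit is used deliberately because natural spline
smoothing forces zero curvature at the body ends and was measured to bias
mean curvature by about −10%. On rendered fixtures the final pipeline
recovers arc curvature within ~1% (R = 40–60 px) and is exactly rotation
invariant.

Curvature itself is computed on the path **resampled to 20 points equally
spaced in arclength**: each triple of adjacent points defines a
circumscribed circle (curvature `4K / abc` with side lengths `a, b, c` and
triangle area `K`; triples with area below `1e-9` px² count as straight),
giving 18 local curvatures whose mean, multiplied by body length, is the
**dimensionless curvature**: 0 for a straight animal, `L / R` for a
circular arc. Frames whose body length falls below **80% of the average**
(whole-video mean by default, running mean optionally) are discarded as
self-coiled or mis-segmented (`video_posture()`).

`curvature_by_state()` smooths the per-frame dimensionless curvature over
20 s (skipping invalid frames) and averages it separately inside and outside
the detected sleep bouts; quiescent animals hold a tighter bend.

## Fluorescence

`delta_f_over_f()` smooths a raw trace over 3 s, takes the running minimum
as baseline `F0(t)` and returns `dFF = (F - F0) / F0`, which is non-negative
by construction and requires a strictly positive baseline (violations
raise an error rather than silently producing infinities).

`delta_r_over_r()` forms the ratiometric signal for two-channel recordings:
`R = dFF_gcamp / max(dFF_mkate, 0.01)` — the floor guards the denominator,
which is exactly zero wherever the reference trace touches its running
minimum — with baseline `R0` the 20th percentile of `R` and
`dRR = (R - R0) / R0`. Because the calcium indicator reports activity while
the reference fluorophore does not, the ratio cancels motion and bleaching
common to both channels.

ROI conventions: a single neuron is an 8×8 square around its tracked center
(`extract_neuron_trace()`); a sleep-neuron soma is read as the mean of the
**20 brightest pixels in a 25×25 window** around the centroid
(`extract_ris_trace()`), robust to small centroid errors. Behavior in
whole-brain recordings is the mean per-frame displacement of the tracked
neurons, smoothed and normalized exactly like a frame-subtraction trace
(`displacement_behavior()`).

`windowed_correlation()` splits behavior and fluorescence into consecutive
**10-min windows**, computes the Pearson correlation within each, and, as a
control, recomputes the correlations after permuting the pairing of
fluorescence windows to behavior windows (5000 random permutations). The
identity permutation is allowed by default; with `K` windows this leaves a
residual of about `mean(r) / K` in the shuffled distribution, which the
package documents rather than hides (`exclude_identity = TRUE` enforces
derangements when a strictly unbiased null is wanted). Windows in which
either series is constant are skipped with a warning.

## Stimulus responses

The state of an animal just before a stimulus is the mean unsmoothed
activity over the **10 s before** stimulus onset (`classify_pre_state()`):
`sleep` below 0.08, `high_wake` above 0.35, `low_wake` in `[0.08, 0.35]`
with both boundaries inclusive. The distinction matters because an animal
already moving near its maximum cannot show a detectable increase. The
response is the mean activity over `(stim + 2 s, stim + 10 s]`
(`post_response()`): the first 2 s are excluded because pressurizing the
valves displaces the animal and inflates apparent movement (light stimuli
move nothing and use `artifact_s = 0`). Trials whose windows extend outside
the recording are dropped (`stimulus_trials()`).

`fraction_awake()` scores a trial as awake when its post-stimulus mean
exceeds the sleep threshold of the geometry in use, and attaches a
**bootstrap standard deviation** (5000 resamples of the trials with
replacement). `resampling_test()` compares two groups of binary outcomes by
permutation: pooled outcomes are relabeled uniformly at random preserving
group sizes — for binary data the group-A success count is then exactly
hypergeometric, which is how the permuted differences are drawn — with the
two-sided Monte-Carlo p-value `(1 + #{|d*| >= |d|}) / (1 + n_iter)`,
Bonferroni-multiplied and capped at 1. The exact permutation null is
discrete, so for small binary groups the achieved type-I error sits below
the nominal level; this conservatism is inherent to exact tests, not a bug.

## Nuclear puncta

`count_puncta_frame()` counts bright nuclear puncta in a fluorescence frame:

1. subtract the animal-free background image (clamped at 0);
2. find the body: 3×3 median filter, Otsu threshold, largest connected
   component, bounding-box ROI. The Otsu split is computed on the image
   **clipped at its 95th percentile**: puncta are far brighter than the
   body, and on an unclipped histogram Otsu separates puncta from everything
   else instead of body from background (measured failure: threshold landing
   just above the body grey level, reducing the "body" to a single punctum).
   Puncta occupy well under 5% of pixels, so the clip never affects the
   background/body classes;
3. sharpen the (un-medianed) subtracted image with a 3×3 unit-DC kernel
   (center 17/9, neighbors −1/9): uniform regions pass through unchanged
   while compact bright objects gain contrast. A zero-sum highpass is
   deliberately not used — it reduces a uniform blob to its edge ring,
   which would let oversized aggregates masquerade as size-gated puncta.
   The median image is used only for body detection because a 3×3 median
   erases objects at the small end of the size gate;
4. binarize at `mean + 3 SD` of the filtered ROI, label 8-connected
   components, and count those with **2–30 px** area (both ends inclusive).

A timepoint is imaged as a burst of 7 frames; movement blurs some frames and
depresses their counts, so the reported value is the **mean of the 3 largest
per-frame counts** (`aggregate_timepoint()`).

The synthetic fixture (`render_puncta_image()`) places non-touching blobs of
exactly known pixel area (the `a` grid pixels nearest a random center)
inside a body ellipse, with optional out-of-range distractors (for example
1 px and 40 px) that appear in the image but not in the truth table. The
counting pipeline recovers these images exactly: counts and component areas
match truth, distractors are never counted.

## Synthetic generators: defaults and rationale

The generators are the ground-truth side of every validation and their
defaults are fixed study conditions, chosen once from design analysis:

- `sample_bout_schedule()`: wake durations exponential with mean **240 s**;
  sleep durations **30 s + Exp(360 s)** (truncated below at the minimum
  scoreable bout, so mean bout length is 390 s). These give a sleep
  fraction near 0.6, typical of confined animals, and — because the 20-s
  smoother trims ~14–17 s per bout — a pooled total-sleep deficit of about
  4%, which the recovery tests measure rather than assume away. Twitches
  occur at **0.5/min of sleep**, last **1–10 s**, and are thinned to ≥30 s
  apart so distinct twitches remain distinct after smoothing.
- `schedule_activity_trace()`: wake counts ~**300** changed pixels (5%
  noise), sleep at the sensor floor (~2), twitches at **35% of wake** —
  low-amplitude movement that must be merged into its bout, not scored as
  wake. With these levels a 10-s twitch produces a supra-threshold
  excursion of at most ~13 s (< 15 s, always merged) while a 20-s full-wake
  interruption produces ~34 s (always splits), exercising both sides of the
  merge rule.
- `render_worm_video()`: a 60-px worm in a 64×128 chamber at 3 fps; wake is
  a traveling sinusoid (amplitude 6 px, wavelength 50 px, 0.5 Hz), sleep a
  frozen circular arc whose dimensionless curvature is **1.15× the mean
  wake curvature** — measured with the same 20-point circle-fit formula the
  posture module uses, so posture truth and estimate share one definition.
  Twitches rock the frozen posture by 1.5 px.
- `simulate_fluorescence()`: ordinary neurons drop to **0.4×** their wake
  level during sleep; a sleep-active neuron instead rises **2×**; a
  state-independent red reference channel shares the common
  `exp(-t / tau)` bleach factor, which the dR/R ratio must cancel.

## Numerical conventions, in one place

- Percentiles: quantile type 7 (linear interpolation) everywhere.
- Intervals: half-open `[start, end)`; series index `i` covers
  `[(i-1)/fps, i/fps)`; window lengths in frames are `round(s * fps)`.
- Moving averages: centered, truncated (renormalized) at the edges; even
  windows put the extra sample after the center.
- Thresholds: activity and quiescence comparisons are strict (`>` / `<`);
  the puncta size gate and the `low_wake` band are inclusive.
- Randomness: every stochastic function takes a `seed` argument
  (`NULL` = caller-controlled RNG stream); seeded calls restore the RNG
  state afterwards.
- Manifest and CSV outputs are deterministic: identical inputs produce
  byte-identical files.

## Limitations

- The activity smoother trades boundary sharpness for robustness: per-bout
  onsets carry a systematic inward shift of roughly half a window, and
  bouts within ~15 s of the scoring minimum can be gained or lost at the
  filter edge. Pooled totals are accurate to a few percent.
- Centerline extraction assumes a single non-self-intersecting animal;
  coiled postures are rejected by the body-length gate rather than
  resolved. The degree-8 path fit limits posture bandwidth to ~4 bends per
  body; shallow arcs (dimensionless curvature below ~0.6) carry relative
  errors up to ~10%.
- The window-shuffle correlation control includes the identity permutation
  unless told otherwise; its small residual bias is documented above.
- The permutation test is exact and therefore conservative for small
  binary groups.
- The synthetic worm video models planar postures of constant brightness;
  it does not emulate out-of-plane rolling, occlusion, or illumination
  gradients.
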