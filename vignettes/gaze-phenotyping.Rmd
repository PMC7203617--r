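---
title: "Gaze and emotion-response phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze and emotion-response phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogaze)
```

## The problem

Children with autism spectrum disorder (ASD) tend to allocate less visual
attention to faces than neurotypical (NC) children, and to differ in how
they recognize facial emotion. `phenogaze` implements an end-to-end
analysis for studies that probe both effects at once with a wearable eye
tracker: a child views a sequence of facial-emotion stimuli, each flanked
by two high-autism-interest distractor images, names the emotion, and the
eye tracker records where they looked. The pipeline quantifies distraction
(gaze on the flanking images instead of the face), tests for group
differences, and asks whether gaze and emotion-response features together
can classify ASD versus NC at the individual level.

Because raw recordings from such studies are rarely shareable, the package
ships a first-class synthetic-session generator with the same statistical
skeleton, so every downstream stage is testable without any data download.
Real data in the same tabular formats can be substituted at any stage
boundary.

## The session design

A session has three trials of 41, 42 and 41 stimuli (124 total). Each
stimulus is shown for 6 s; in the second trial the correct emotion is
announced after 3 s (the feedback trial). The facial stimulus occupies
49% × 87% of the screen, centered; each distractor occupies 17% × 31%,
centered in the strips beside the face (`screen_geometry()`; the source
layout gives sizes but not positions, so the symmetric centering here is a
package choice). After every complete block of eight stimuli a validation
dot appears at screen center for 5 s; it anchors both calibration
validation and epoch assignment. All screen coordinates are normalized to
the unit square, origin top-left.

The printed stimulus total in the source protocol (125) is inconsistent
with the per-trial counts (41 + 42 + 41 = 124); the per-trial counts drive
every downstream feature dimensionality, so they are authoritative here.

## The generative model

**Cohort.** Each participant carries a latent per-frame distraction
propensity and an off-task propensity, both Beta-distributed with moments
matched to the configured group mean/SD (`make_cohort()`). The defaults
reproduce the reported group distraction statistics (ASD mean 0.0433, SD
0.0911; NC mean 0.0139, SD 0.0215), the group gender ratios (13/16,
9/17), and age ranges. Moment matching fails loudly when the requested SD
is impossible for a Beta with the requested mean. Clinical-score columns
(SCQ, SRS, ABIQ) are generated as inert metadata in realistic ranges and
are never consumed by any analysis stage.

**Gaze.** Within each stimulus window the latent gaze target follows a
first-order Markov chain over {face, left distractor, right distractor,
nowhere} with kernel `dwell * I + (1 - dwell) * 1 pi'`. This kernel keeps
the stationary distribution exactly at `pi` — distractor mass equal to the
latent distraction propensity, split evenly left/right — for any dwell, so
the dwell parameter (default 0.9) shapes fixation run lengths without
biasing frame fractions. The initial state of each window is drawn from
the stationary distribution, modeling a persistent attention state; this
also makes the expected distractor frame fraction equal the latent
propensity exactly, which the parameter-recovery tests rely on. Emitted
coordinates are the target region's center plus isotropic Gaussian noise
(default SD 0.01 normalized units, small against the distractor half-width
of 0.085). "Nowhere" frames emit a uniform point outside all regions by
default, or a missing value under the `missing` policy — both occur in
real eye tracking and the coder handles both.

**Calibration truth.** The session is partitioned into four epochs
(emulating recalibration before the task and after each trial), each with
its own affine pupil-to-world mapping drawn with mild scale and offset
drift. Affine truth keeps the inverse mapping — needed to synthesize pupil
coordinates from world coordinates — available in closed form; the fitting
side supports polynomial degrees 1–3 regardless, and quadratic recovery is
tested on pairs generated directly from quadratic maps, where no inversion
is required. Explicit calibration-pass data (a 3 × 3 grid of fixated
targets per epoch) is synthesized by `simulate_calibration_pairs()`; a
validation dot alone cannot identify a mapping, since it provides a single
world target.

**Responses.** Each participant owns a 7 × 7 row-stochastic confusion
profile (diagonal accuracy Beta-distributed per group, off-diagonal mass
uniform). On the feedback trial the response row is interpolated toward
the correct answer: `row' = (1 - boost) * row + boost * e_true`, so
`boost = 1` makes every feedback-trial response correct.

What the generator deliberately does **not** model: head movement and
chinrest effects, eye/mouth sub-regions within the face, blink structure,
saccade kinematics, and any dependence of gaze on the specific emotion
shown. Passing tests therefore demonstrate the correctness and calibration
of the *analysis machinery* under the study's statistical skeleton, not
robustness to every artifact of real recordings.

## Pupil detection

Three detectors cover complementary failure modes on eye-camera frames:

- `detect_mser()` sweeps intensity thresholds and scores connected dark
  components by stability (relative area growth across neighboring
  thresholds), with area gates (0.5%–20% of the image) and an
  eccentricity gate (≤ 2.5) that exclude speckle and eyelid-like
  elongated shadows. Region centroids localize with subpixel precision.
- `detect_gradient()` maximizes the mean squared alignment between
  displacement directions and image gradients, weighted toward dark
  centers, over a stride-2 grid refined to unit resolution. The exhaustive
  objective is quadratic in pixel count; restricting it to
  strong-gradient pixels (top decile) and coarse-then-fine search keeps
  the accuracy loss below the 1 px gate.
- `propagate_flow()` translates the previous center by iterative
  Lucas–Kanade flow in a local window, with confidence decaying in the
  post-warp residual.

`fuse_estimates()` combines them by **gate-and-validate**: when the
gradient estimate corroborates the top stable-region candidate within the
gate radius (3 px), the fused center is that candidate's centroid and the
confidence is boosted; otherwise the highest-confidence single estimate
wins, then flow, then the frame is marked untrackable. The centroid — not
an average of the two estimates — is kept deliberately: the region
centroid is the more precise localizer (~0.1 px on rendered fixtures,
versus ~0.4–2 px for the grid-refined gradient objective), so averaging
would strictly worsen the fused error; the gradient objective's role in
the hybrid is validation. This keeps the fused tracker at least as
accurate as every single method across the tested noise range.

## Calibration and epoch assignment

`fit_calibration()` is per-axis least squares over the full bivariate
monomial basis (default degree 2 — the standard choice for monocular 2-D
regression calibration — configurable 1–3), with explicit rank checking.
The world targets are the *assumed* true gaze directions, following the
protocol's stated assumption that the participant looks at the on-screen
target.

Human inspection of "which calibration model applies when" is replaced by
a deterministic rule (`assign_epochs()`): the session is cut into segments
at validation-dot onsets; each candidate model is scored per segment by
its best adjacent-dot median prediction error, and the best model wins the
segment unless its error exceeds a threshold, in which case the segment
gets no model and its frames are dropped from coding. The default
threshold is geometry-derived — half the face region's half-width
(0.1225) — because a calibration worse than that cannot distinguish face
from distractor anyway.

## Distraction statistics

Each stimulus-window frame is coded `F`, `L`, `R` or `N` by inclusive
rectangle membership (missing and off-screen → `N`). Per stimulus,

- `d = (nL + nR) / (nF + nL + nR + nN)` — distraction ratio over all
  attributed frames, and
- `d_flr = (nL + nR) / (nF + nL + nR)` — the variant excluding `N` frames
  from the denominator, undefined when no frame hit any region.

Only this reading makes the two definitions differ in the documented way
(`d ≤ d_flr` always). Per-participant `d(p)` is the unweighted mean over
valid stimulus records — stimuli weighted equally, so trials with more
surviving stimuli weigh more; weighting trials equally instead is a
defensible alternative the package does not take. Trials with a trackable
fraction below 0.5 are dropped outright (`exclude_outliers()`), an
explicit, configurable surrogate for discard-on-inspection.

The group comparison is a one-tailed Welch test (ASD mean > NC mean);
Welch is the default because the two groups' spreads differ several fold,
with the pooled-variance test behind a flag. The same routine serves the
exploratory per-stimulus comparison, which records in its output that it
assumes within-participant independence — an assumption the study design
itself flags as unreasonable.

## Features and classification

Per trial with `S` stimuli: 49 confusion-matrix entries (rows normalized;
empty rows left at zero and flagged), `S` per-stimulus correctness
binaries, `3S` gaze features, plus 2 metadata features (age; gender coded
male = 0) — `4S + 51` columns, i.e. 219 for the 42-stimulus trial. The
gaze triple per stimulus: fraction of on-region frames on the face;
fraction of distinct-code transitions whose destination is the face; and
frames elapsed before the first face fixation (window length if never).
Concatenation across trials includes the metadata block once — duplicated
copies would be degenerate under standardization.

Classification is leave-one-participant-out: imputation (per-column
training-fold medians), standardization (training-fold statistics), and
hyperparameter search (5-fold inner cross-validation over the mixing and
penalty-strength grid, misclassification loss) are all confined to each
training fold, so no information about the held-out participant leaks into
the fit. The elastic net is penalized logistic loss by default; a
squared-loss variant thresholded at 0.5 (`linear_net`) is available, and
pure-l1/l2 logistic ablations mirror the grid-search design. A predicted
score of exactly 0.5 ties to NC by convention.

`shuffle_test()` permutes group labels at the participant level — the
exchangeable unit under LOPO — re-runs the full pipeline per permutation,
and reports the add-one p-value `(1 + #{null ≥ observed}) / (B + 1)`,
which can never be zero. For a fixed-penalty linear ridge the LOPO
prediction is an exact linear operator in the label vector (imputation
and standardization depend only on the features), so all permutations are
evaluated with one matrix product; a test proves this fast path equal to
explicit refitting. Accuracy over n participants is discrete, so ties
between null and observed accuracies make the p-value mildly
conservative — the calibration test accounts for this by checking the
rejection rate against the exact binomial band rather than a point value.

## Problem sizes and numerical choices

The test suite exercises the pipeline at the study's own scale where the
property demands it (16 + 17 participants, the 41/42/41 schedule, 200
seed replicates for parameter recovery, 200 × 199 permutations for
shuffle calibration) and at reduced scale where only correctness is at
stake (8-stimulus schedules for round trips, 14-stimulus single trials
for planted-signal ranking). Degenerate inputs are handled by explicit
convention rather than silently: both-groups-constant tests return
p = 0.5 flagged, all-zero count rows are invalid and excluded from
aggregation, all-dropped windows impute all three gaze features, and
zero-gradient images return confidence 0.

## Known limitations

- The synthetic gaze model has no within-window nonstationarity (no
  novelty decay, no saccade-latency structure), so latency features carry
  less signal than they might in real data.
- The eye-camera frame rate of the source protocol is unstated; 30 fps is
  a configuration default.
- Whether the feedback trial's 6 s window should be split around the 3 s
  audio cue is unstated; all trials use uniform 6 s windows.
- Epoch assignment is at inter-dot granularity; a mapping switch strictly
  between dots is attributed to one of the adjacent segments.
- The pupil renderer draws a clean disk with additive noise; it contains
  no glints, eyelids, or blinks, so detector accuracies on it are upper
  bounds.
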