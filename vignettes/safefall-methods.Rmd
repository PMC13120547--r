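---
title: "Quantifying fall quality from 2D pose sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fall quality from 2D pose sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safefall)
```

## The problem

Whether a person falls *safely* — lowering the centre of mass deliberately,
tucking the chin, converting vertical impact into a horizontal roll — or
*hazardously* — freezing upright, bracing on outstretched arms (FOOSH),
flailing — is visible in the kinematics of a tracked 2D skeleton.
`safefall` turns tracked pose sequences (17 COCO keypoints per frame, with
confidences and bounding boxes, as produced by modern top-down pose
estimation pipelines) into interpretable biomechanical metrics, a composite
safety score, and the three standard analyses built on them: pre/post
intervention statistics, latent motor-profile clustering, and
subject-independent fall-quality classification.

All coordinates are image coordinates: origin at the top-left corner,
y increasing downward. *Descent is therefore positive vertical velocity.*

## Data model and repair

A `fall_sequence` stores one identity's frames: a `n x 17 x 3` keypoint
array (x, y, confidence), a visibility mask, per-frame bounding boxes,
frame rate, frame size, cohort tag and an optional safe/hazardous label.
COCO-17 includes neither a chin nor a sternum keypoint, so the
neck-protection distance uses the closest stable proxies: the nose for the
chin and the shoulder midpoint for the sternum. This overestimates the
absolute chin–sternum distance but preserves its contrasts — chin tucking
moves the nose toward the shoulder line.

`repair_gaps()` masks keypoints below a confidence floor (default 0.5, the
conventional upstream detection threshold) and linearly interpolates
invisible runs of at most 10 frames (~167 ms at 60 fps, deliberately
shorter than the impact window so an imputed stretch can never span the
impact). Ends are never extrapolated; imputed keypoints are flagged and
their confidence set to the floor, which makes the repair idempotent.

## Kinematic signals and metrics

The vertical hip velocity is the backward finite difference of the mid-hip
height scaled by the frame rate,
$v_y(t) = (y_{hip}(t) - y_{hip}(t-1)) \cdot \mathrm{fps}$, in pixels/second.
Planar speed and acceleration magnitude are computed from mid-hip
coordinates smoothed by a centered moving average (default width 5 frames):
raw second differences of pixel coordinates at 60 fps are noise-dominated,
and a 5-frame window stays well inside the 25-frame impact window.
Positional metrics (ranges, variabilities) use the raw trajectory.

Eighteen sequence-level metrics are aggregated over the full fall episode,
in three categories plus postural extras:

* **Movement** (9): average/max planar velocity and acceleration, movement
  range in x and y, high-movement frame count, movement intensity, average
  keypoint confidence.
* **Stability** (3): position variability in x and y (standard deviations),
  velocity variability.
* **Fall** (3): average and maximum descent rate (positive part of
  $v_y$; the average over the whole window with zeros included, so
  hesitation dilutes it), total vertical change (max − min mid-hip height,
  intentionally identical to movement range y).
* **Postural** (3): mean trunk inclination (angle between the upward
  vertical and the hip→shoulder vector; 0° upright, 90° horizontal),
  maximum bounding-box aspect ratio (width/height; above 1 indicates a
  lying posture), minimum neck-protection distance.

The *high-movement* threshold `tau_move` is 15 px/frame of mid-hip
displacement. It is deliberately high: typical controlled descents peak
near 13 px/frame, so only abrupt, high-energy movement registers, and both
the count and the intensity have median 0 across a normal cohort — matching
how these coarse activity counters behave in practice.

## Phase segmentation

The impact phase is a ±200 ms window around the peak hip deceleration,
i.e. ±`round(0.2 * fps)` frames (±12 at 60 fps). The descent episode is
located on the smoothed vertical velocity as the contiguous run above a
motion floor (default 40 px/s) with the largest total descent; the
peak-deceleration frame is the most negative smoothed vertical acceleration
within that episode (extended by one smoothing window, since the
deceleration tail can outlast the above-floor run). Degenerate case: a
constant-velocity descent has no deceleration anywhere, and the detector
then returns the first frame of the episode — the descent onset — as the
documented convention. A sequence in which nothing exceeds the motion floor
raises a no-fall error from `segment_phases()`, while `extract_metrics()`
still returns (zero-motion) metrics with `segmentable = FALSE`.

## The synthetic fall generator

The study conditions this package targets — school-gym recordings of
backward falls at 60 fps, 1920×1080, cohorts of 285 pre-test and 130
post-test children — involve video of minors that cannot be shared, so the
package ships a generator that emulates pose-estimator output for three
motor profiles:

* **controlled** (tuck-and-roll): rapid squat flowing into a full 190 px
  descent (0.8 s total), a 350 px horizontal roll, chin tuck 0.9, arms
  tucked;
* **chaotic**: near-step 220 px descent (0.3 s), 6 Hz sinusoidal flail of
  ±60 px on wrists/elbows/ankles with an attenuated slow pelvis wobble,
  chin untucked;
* **freezing**: 0.8 s hesitation, slow shallow descent (100 px over
  1.6 s), no roll, straight extended arms (FOOSH-like), chin untucked.

All profiles share a slow whole-body lateral balance sway (±50 px at
~0.35 Hz) so that spatial-range metrics have realistic within-group
variance instead of degenerate zero-variance groups.

The skeleton is a 2D stick-figure forward-kinematics template: a torso
segment, head offset and four two-segment limbs driven by the hip-centre
trajectory and a trunk-rotation schedule. The hip descent follows a quintic
"smootherstep" ramp, which is C2-continuous: its deceleration peak lies in
the interior of the ramp rather than at a corner, giving the template a
well-defined peak-deceleration frame that symmetric smoothing recovers
without bias. Gaussian keypoint noise (default sd 2 px) and Bernoulli
dropout (default 2% per keypoint-frame) are applied last, so with both at
zero a generated sequence *is* its closed-form template, and the template's
peak-deceleration frame, phase boundaries and quality label (controlled →
safe, others → hazardous) are stored as ground truth.

Cohort mixes default to pre = (0.10 chaotic, 0.55 controlled,
0.35 freezing) and post = (0.02, 0.83, 0.15): the intervention shifts
membership toward the controlled profile, with per-subject log-normal
jitter (sd 0.15) on magnitudes and timings so profiles overlap
realistically. Because a membership shift alone cannot reproduce the
within-subject training effect — a rank-based comparison of any
descent metric between two mixtures that differ by 20 points of freezing
share is bounded near AUC 0.6 — the cohort model additionally applies a
commitment effect to post-test subjects: descent depth ×1.2 (capped by the
stance geometry) and fall duration ÷1.1. This mirrors the intervention's
documented signature (decisive lowering of the centre of mass) and is what
makes the fall-category contrasts detectable at realistic sample sizes.
These settings reproduce orderings and significance structure, not any
particular published effect magnitude.

What the generator does *not* emulate: genuine pose-estimator failure modes
(identity switches, long occlusion dropouts, systematically displaced
joints), anthropometric variation beyond isotropic scaling jitter,
camera-perspective distortion, and multi-person interaction. Tests passing
on synthetic cohorts therefore validate the analysis chain, not the
upstream perception stack.

## The composite safety score

$S_{safe} = \sum_j w_j f_j$ over selected, normalized, direction-aligned
features. The hybrid construction:

1. **Selection (hypothesis-driven):** Cohen's d between hazardous and safe
   groups, pooled-sd definition with n−1 variances; features with
   |d| ≥ 0.5 (a medium effect — configurable) are retained, each oriented
   so that +1 means larger-is-safer.
2. **Weights (data-driven):** mean decrease in Gini impurity from a
   100-tree random forest on the retained features, renormalized to sum
   to 1.
3. **Normalization:** min–max to [0, 1] between the 2.5th and 97.5th
   percentiles of the fitting cohort, with clipping — percentile anchors
   are robust to simulator outliers, and clipping keeps the score in
   [0, 1].

The score is monotone in every direction-aligned feature by construction.
Labels come from generator ground truth for synthetic data or a
user-supplied column for real data.

## Cohort statistics

Per metric: a Shapiro–Wilk normality gate per group (recorded; a constant
sample is flagged as degenerate and treated as non-normal), then the
two-sided Mann–Whitney U test — exact when both groups have ≤ 20
observations and no ties, tie-corrected normal approximation otherwise.
Benjamini–Hochberg correction is applied across the 15-metric family;
Cohen's d and percent change accompany the p-values. Percent change is
computed on medians for consistency with median-based reporting, and the
mean-based change is reported alongside because the two can differ
materially in skewed metrics. With both cohorts identical the chain is
calibrated: across 100 replicate null cohorts, at most ~5–10% show any
BH-significant metric at α = 0.05.

## Motor profiles and classification

Clustering operates on the 15 z-standardized sequence-level metrics
(unscaled pixel metrics would dominate the Euclidean geometry): PCA for the
variance spectrum and 2D projection, then k-means with k = 3, 10 random
starts, best by within-cluster sum of squares. Clusters are relabelled
canonically by descending movement-intensity centroid (ties by descending
average descent rate), so "cluster 1" is always the chaotic-like profile,
"cluster 2" the controlled one and "cluster 3" the freezing one, stable
across seeds. Cluster profiles are reported as percent deviation of the
cluster mean from the sample mean (undefined when the sample mean is 0,
reported as NA), and the cohort×cluster association uses Pearson's
chi-square without continuity correction.

Supervised evaluation is subject-independent: subjects (never rows) are
partitioned into k folds (greedily label-balanced when stratified), or one
fold per subject (LOSO). Five models are compared — random forest
(100 trees, Gini), gradient boosting (100 rounds, learning rate 0.1,
depth 3), ridge logistic regression (λ = 0.01 on standardized features),
RBF-kernel SVM with probability outputs, and a single-hidden-layer
perceptron (16 units, weight decay 10⁻³ as the regularizer, since the
underlying optimizer has no early stopping). Class imbalance is handled by
reporting imbalance-robust metrics (macro-F1, AUC) rather than by
resampling. Frame-level reports include a subject-aggregated pooling (mean
predicted probability per subject) because deployment decisions are made
per fall, not per frame. Random-forest impurity importances are averaged
over folds and renormalized.

## Numerical choices and degenerate inputs

* Backward differences everywhere, NA (or zero-padded, in the frame-level
  feature matrix) before they exist; second derivatives are computed as
  differences of first derivatives so they equal a naive two-pass loop
  bit-for-bit.
* Confidences outside [0, 1] and coordinates outside the frame are clamped
  with a warning at validation, mirroring tolerant consumers of estimator
  output.
* Coincident hip/shoulder landmarks give an undefined trunk angle (NA with
  a warning); zero-height boxes are an error.
* Identical observations in both groups short-circuit the Mann–Whitney
  test to p = 1.
* Constant metric columns are dropped (with a warning) before PCA/k-means
  and refused an effect size during score fitting.

## Problem sizes used by the tests and the acceptance script

The packaged checks run cohorts at the study's default conditions
(285/130 subjects, 3 s clips at 60 fps) for the effect-detection,
clustering and scoring properties; calibration nulls use 100 replicates of
40/40-subject cohorts (type-I behaviour does not depend on n); and the
five-model frame-level comparison runs on a 40/20-subject cohort with
every 4th frame, which keeps the full comparison tractable on one CPU
while preserving strictly subject-independent folds. These sizes are the
package's own trade-off between statistical resolution and runtime.

## Known limitations

* 2D pixel kinematics: no camera calibration, so velocities are in
  pixels/second and comparisons assume a consistent viewpoint and scale.
* The chin/sternum proxies bias the absolute neck-protection distance.
* The generator's stick figure is not a biomechanical model; it induces
  the metric structure the analyses consume, nothing more.
* Peak-based metrics inherit the sensitivity of second differences to
  noise even after smoothing; they are reported but are the least stable
  part of the metric vector.
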