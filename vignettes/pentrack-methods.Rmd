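---
title: "Methods: pen monitoring from bounding-box detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pen monitoring from bounding-box detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrack)
```

## The problem

Commercially housed pigs express health and welfare through posture and
drinking behaviour: reduced standing, increased lateral lying or altered
drinking can precede clinically visible disease. A ceiling camera over a
pen, combined with a per-frame object detector, reduces video to a stream
of bounding boxes, each labelled with one of five mutually exclusive
behaviours (standing, sitting, lateral lying, sternal lying, drinking)
and a confidence score. `pentrack` starts where the detector ends: it
takes per-frame detections and produces anchor-box priors, multi-animal
tracks with stable virtual identities (vIDs), group-level behaviour
indices with baseline comparisons, individual locomotion profiles, and
the standard detection/tracking evaluation metrics. The detector itself
is a pluggable contract — any function producing a valid detections table
works — and a seeded pen simulator serves as its reference
implementation for testing.

## Geometry conventions

Boxes are `[x y width height]` with `(x, y)` the upper-left corner,
origin at the image's upper-left, y downward, 0-based, and a box covering
the continuous region `[x, x+w] x [y, y+h]`. IoU uses continuous areas;
boxes that merely touch have IoU 0. These choices match evaluation
practice and avoid the off-by-one ambiguity of pixel-index conventions;
if externally annotated data with a 1-based convention is imported, the
caller must shift coordinates (there is no auto-detection).

## Anchor estimation

Anchors are shape priors `(w, h)`; positions are irrelevant, so
clustering works on shapes with the distance `1 - shape_iou`, where
`shape_iou` co-aligns the two boxes at a common corner. `1 - IoU` is not
a metric (the triangle inequality can fail), which is one reason for
K-medoids over centroid-based methods; the other is robustness: a medoid
is an actual training shape, so outlier boxes cannot drag an anchor off
the data manifold.

The optimiser is PAM (swap descent) from a seeded greedy farthest-point
initialisation, best of `restarts = 20` runs, ties broken by total
distance then lexicographic anchor order — fully deterministic per seed.
The anchor-count sweep (`anchor_sweep`, default `k = 1..15`) warm-starts
each `k` with the previous solution's medoids as one initialisation
candidate. Because the quality measure (mean over boxes of the best
shape IoU against any anchor) is an affine transform of the clustering
objective, a warm start can never do worse than the previous `k`, and
the sweep curve is guaranteed non-decreasing. The quality mean is
box-weighted (every training box counts once); an unweighted per-cluster
average was the other defensible reading and is not implemented.

## Tracking-by-detection

Per recorded frame:

1. every live track is predicted by a constant-velocity Kalman filter on
   the box centroid (state `(cx, cy, vx, vy)`), box extents carried from
   the last assigned detection;
2. the cost matrix `1 - IoU(predicted box, detection)` is gated at
   `gate_iou_min = 0.3` (gated pairs are unassignable);
3. the Munkres/Hungarian solver finds the global minimum-cost assignment
   with a `cost_of_non_assignment = 0.7` penalty per unmatched track or
   detection;
4. assigned tracks are measurement-updated and take the detection's
   behaviour class; unassigned detections spawn *tentative* tracks;
   tentative tracks reaching `M = 3` consecutive hits become
   *confirmed*; a tentative track is deleted on its first miss (it may
   be a false detection); confirmed tracks coast on the prediction
   (class carried, samples flagged `coasted`) for up to `L = 10`
   consecutive misses, then die.

Only ever-confirmed tracks are reported, including their tentative
prefix, so an animal detected from frame 1 has a full-length history.
`M` and `L` are engineering defaults — the observation that inspired the
lifecycle scheme never quantifies either — and are exposed in
`tracker_config()`. The motion model is centroid-only because lying pigs
are stationary and walking pigs move smoothly at 25 fps; filtering box
extents adds state without testable benefit. Coasting counts recorded
frames, not wall-clock time, since dropped frames are simply absent from
the stream and the association machinery is frame-indexed. Identity is
never reused; re-entering animals legitimately receive new vIDs.

Kalman noise defaults (`process_noise = 0.01`, `measurement_noise = 1`,
in px²) favour smooth constant-velocity extrapolation; on a noiseless
constant-velocity target the one-step prediction error falls below half
a pixel within ten updates.

## Behaviour analytics

The behaviour index of a window is `BH = sum_k NBF_k / N`: the mean
number of animals showing the behaviour per *recorded* frame. Counting
only recorded frames makes windows with different amounts of frame loss
comparable. Group-level indices are computed directly from detections —
no tracking required — because frame-wise pen counts are robust to
identity errors; individual profiles require tracks. Both share the same
counting core.

Percent change is `100 (BH - baseline) / baseline`. The default
baseline is the mean index over the preceding control days
(`mode = "pre_days"`); averaging the pre- and post-disruption days is
exposed as `pre_and_post_mean` since both framings are standard.

Individual profiles use the box centroid as the animal position. Total
distance is the summed Euclidean displacement between consecutive
centroids; mean speed divides by elapsed *wall-clock* time, so dropped
frames do not inflate speed. Coasted samples keep the trajectory
continuous but are excluded from time budgets, which count detected
behaviours only — a coasted class label is a guess, not an observation.
Distances are in pixels; an optional metres/pixel scale is accepted but
no default is asserted, because a camera-to-floor projection cannot be
recovered from box data alone.

## Evaluation

Detection: true positives require IoU ≥ 0.5 (configurable; the
convention, not a value taken from any particular study). Matching
within a frame is greedy by descending score, each detection taking the
unmatched ground truth of highest IoU. AP is the all-points area under
the precision-recall curve (not 11-point interpolation — the two differ
by 1–2% and the choice is declared here). The log-average miss rate
samples miss rate at 9 log-spaced FPPI reference points in `[1e-2, 1]`,
clips at `1e-10`, and takes the geometric mean.

Tracking: CLEAR metrics. Per frame, ground truth and predictions are
matched with persistence (previous pairings kept while still above the
IoU gate) plus optimal Hungarian matching of the remainder; an identity
switch is counted when a ground-truth animal's matched predicted
identity changes relative to the last identity it ever matched.
`MOTA = 1 - (FN + FP + IDSW) / GT`. MOTP is reported as the mean IoU of
true-positive matches (higher is better): the alternative reading of
"distance between target and annotation" as a raw intersection area is
dimensionally inconsistent, and a published MOTP of 0.80 only reads
sensibly as a normalised overlap; the `1 - IoU` reading is available via
`inverse_motp = TRUE`. Locomotion error is the per-animal MSE of total
distance and of mean speed.

## The pen simulator

The simulator is the package's stated world, not a tuning knob: a
640 × 360 px pen at 25 fps, 15 pigs, 4 nipple drinkers — the recording
geometry of a commercial finisher pen at roughly 160 px/m. Each pig runs
a Markov chain over the five behaviours, constructed as
`P = a I + (1 - a) 1 pi'` so the stationary distribution `pi` is exact
and bout persistence `a` is a single interpretable parameter (default
0.98, mean bout 2 s at 25 fps; scaled-down studies in the tests shorten
bouts rather than lengthen runs). The default budget — standing 0.20,
sitting 0.05, lateral lying 0.35, sternal lying 0.35, drinking 0.05 —
reflects daytime finisher-pig time budgets dominated by lying. Pigs move
only while standing (random-heading walk with wall reflection, 1–4
px/frame); drinking is entered only within `drinker_radius = 15` px of a
drinker, where the box snaps to it; lying and sitting are stationary.
Box shape depends on posture (lateral lying elongated, sitting compact)
and a fixed per-animal size factor, giving anchor clustering real
structure. The radius is deliberately small: the snap displacement must
stay inside the tracker's IoU gate, since goal-directed walking towards
drinkers is not modelled — a known limitation, and the reason realised
drinking dwell is below its nominal stationary mass.

Degradation draws from its own seed (two RNG streams), so one world can
be degraded at several noise levels for paired comparisons: Gaussian
corner jitter, per-box misses, Poisson false positives, class confusion,
and whole-frame drops with surviving timestamps unchanged. With all
rates zero the channel is the identity with score exactly 1. No noise
level is calibrated to any real detector; they are stress-test ranges.

What a green end-to-end test establishes: the pipeline is internally
consistent (zero-noise simulation recovers MOTA = MOTP = mAP = 1 and
exact path lengths) and degrades monotonically under injected noise. It
does **not** establish field accuracy: rigid rectangular pigs, no
occlusion geometry, no illumination effects, and independent per-pig
chains are all simplifications a real pen violates.

## Numerical choices

* PAM tie-breaks: lowest total distance, then lexicographic medoid
  order; all randomness flows through explicit seeds kept local (the
  caller's RNG state is untouched).
* The Hungarian solver pads the rectangular gated problem to a square
  matrix with non-assignment costs on dummy diagonals; forbidden pairs
  carry a large finite cost and are stripped from the solution.
* Kalman covariance updates use the Joseph form and re-symmetrisation,
  keeping the covariance PSD over long coasting runs.
* Degenerate inputs fail loudly: empty box lists, zero recorded frames,
  zero baselines, zero ground truth, and zero matches are errors or
  flagged `NA`s, never silent zeros.
* The disruption analysis in the acceptance suite uses a 4-posture world
  for the frame-drop robustness check, since spatially gated drinking
  has a realised index too close to zero for a relative-deviation bound
  to be meaningful.

## Known limitations

No appearance model: after a track dies, a returning animal gets a new
vID. No occlusion reasoning: overlapping boxes are allowed and stress
the gating, but the simulator does not hide one pig behind another. The
pixel-to-metre calibration is the caller's responsibility. Behaviour
classes are frame-wise labels; no bout segmentation or smoothing is
applied before indices are computed.
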