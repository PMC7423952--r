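# pentrack

Quantifying posture and drinking behaviour of group-housed pigs from
per-frame bounding-box detections.

Precision-livestock monitoring reduces ceiling-camera video of a pen to a
stream of detections: one axis-aligned box `[x y width height]` per visible
pig per frame, labelled with one of five mutually exclusive behaviours
(standing, sitting, lateral lying, sternal lying, drinking) and a
confidence score. `pentrack` implements everything downstream of the
detector, for ethologists and engineers who have such detections (from any
CNN, or from the built-in simulator) and need defensible behavioural
statistics:

* **Anchor estimation** — K-medoids clustering of training-box shapes with
  the distance `1 − IoU(shape_a, shape_b)`, plus the anchor-count/quality
  trade-off sweep. Medoids are actual training shapes, robust to outlier
  boxes.
* **Tracking-by-detection** — per frame, a constant-velocity Kalman filter
  predicts each track's box; the Munkres/Hungarian algorithm solves the
  gated `1 − IoU` assignment with a cost of non-assignment; tracks follow a
  tentative → confirmed → deleted lifecycle (confirm after `M = 3`
  consecutive hits, coast up to `L = 10` missed frames). Each animal keeps
  a stable virtual identity (vID).
* **Behaviour analytics** — the group-level behaviour index
  `BH = (Σₖ NBFₖ)/N` (mean pigs showing the behaviour per recorded frame),
  windowed index series, baseline percent-change analysis, and individual
  profiles: trajectory, time budget, total distance (Euclidean centroid
  path) and mean speed from wall-clock timestamps.
* **Evaluation** — average precision (all-points area under the
  precision–recall curve), mAP, log-average miss rate vs FPPI, and the
  CLEAR tracking metrics `MOTA = 1 − (FN+FP+IDSW)/GT` and MOTP (mean IoU of
  true-positive matches), plus locomotion MSE.
* **Pen simulator** — a seeded 640 × 360 px pen at 25 fps with up to 15
  pigs and 4 drinkers; per-pig Markov chains over the five behaviours,
  movement only while standing, drinking only at a drinker; a degradation
  channel adds box jitter, misses, false positives, class confusion and
  dropped frames. This is the ground-truth source for every test.

## Worked example

```r
library(pentrack)

cfg   <- pen_config(n_pigs = 8, seed = 7)          # the stated world
sim   <- simulate_pen(cfg, 300)                    # ground truth, 12 s
noisy <- degrade(sim, noise_config(jitter_sigma = 1, miss_rate = 0.05,
                                   tp_score_min = 0.6, seed = 8))

kmedoids_anchors(sim$annotations, k = 3, seed = 1)
#> Anchor set: k = 3, mean IoU = 0.9134 (seed 1, 20 restarts)
#>    1: 67.7609 x 38.7205
#>    2: 77.441 x 34.8484
#>    3: 82.2555 x 43.8696

ts <- track_sequence(noisy$detections)
ts
#> Track set: 8 valid track(s), 2400 frame rows, 16 lifecycle events

mot_metrics(sim$annotations, ts$tracks)
#> MOT report: MOTA 1.0000, MOTP 0.9408 | FN 0 FP 0 IDSW 0 / GT 2400 (TP rate 1.0000)

win <- data.frame(window = c("h1", "h2"), start = c(1, 151), end = c(150, 300))
head(as.data.frame(index_series(noisy$detections, win, frames = noisy$frames)))
#>   window         class index n_frames
#> 1     h1      standing  2.55      150
#> 2     h1       sitting  0.00      150
#> 3     h1 lateral_lying  2.02      150
#> 4     h1 sternal_lying  3.08      150
#> 5     h1      drinking  0.00      150
#> 6     h2      standing  1.44      150

build_profile(ts, vid = 1, times = sim$frames)
#> Profile vID 1: 300 samples, distance 363.2 px, speed 30.36 px/s
#>   time budget: standing 0.07, sitting 0.00, lateral_lying 0.88, sternal_lying 0.05, drinking 0.00
```

Reading the output: the three anchors summarise the posture-dependent box
shapes at a mean shape-IoU of 0.91; all 8 simulated pigs are tracked with
zero identity switches despite 5% missed detections (coasting bridges the
gaps), with localisation overlap 0.94 under 1 px corner jitter; the
behaviour indices say that, e.g., on average 2.55 pigs were standing per
recorded frame in the first window; and pig vID 1 spent 88% of its
detected samples lying laterally while travelling 363 px.

A full command-line pipeline is also provided:

```sh
Rscript -e 'pentrack::pentrack_cli()' simulate --out-dir run --pigs 8 --frames 300 --seed 7
Rscript -e 'pentrack::pentrack_cli()' track    --detections run/detections.csv --out-dir run
Rscript -e 'pentrack::pentrack_cli()' evaluate --ground-truth run/annotations.csv \
        --predictions run/tracks.csv --out run/report.json
Rscript -e 'pentrack::pentrack_cli()' demo     --out-dir demo   # synthetic disruption study
```

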