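Package: pentrack
Title: Tracking and Behaviour Analytics for Group-Housed Pigs from
    Bounding-Box Detections
Version: 0.1.0
Authors@R:
    person("Pentrack", "Developers", email = "pentrack@example.org",
           role = c("aut", "cre"))
Description: Detection-agnostic toolkit for quantifying posture and drinking
    behaviour of group-housed pigs from per-frame bounding-box detections.
    Provides anchor-box estimation by K-medoids clustering with an
    intersection-over-union distance, multi-animal tracking-by-detection
    (Munkres/Hungarian assignment with constant-velocity Kalman prediction
    and a tentative/confirmed/deleted track lifecycle), group-level behaviour
    indices with baseline percent-change analysis, individual animal profiles
    (trajectory, time budget, locomotion), a full detection and tracking
    evaluation suite (average precision, log-average miss rate, MOTA, MOTP,
    locomotion mean squared error), and a seeded pen simulator that generates
    ground truth and emulates detector noise for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
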