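test_that("same config and seed give bit-identical output", {
  cfg <- pen_config(n_pigs = 4, seed = 5)
  a <- simulate_pen(cfg, 60)
  b <- simulate_pen(cfg, 60)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  d1 <- degrade(a, noise_config(jitter_sigma = 2, miss_rate = 0.1, seed = 9))
  d2 <- degrade(b, noise_config(jitter_sigma = 2, miss_rate = 0.1, seed = 9))
  expect_identical(d1$detections, d2$detections)
})

test_that("config validation catches impossible worlds", {
  expect_error(pen_config(n_pigs = 0), "n_pigs")
  expect_error(pen_config(drinkers = data.frame(cx = -5, cy = 10)), "inside")
  expect_error(pen_config(stationary = c(standing = 1, sitting = 0.2,
                                         lateral_lying = 0, sternal_lying = 0,
                                         drinking = 0)), "distribution")
  expect_error(pen_config(drinkers = data.frame(cx = numeric(0),
                                                cy = numeric(0))),
               "zero drinkers")
})

test_that("all-lateral identity chain freezes every pig", {
  cfg <- pen_config(n_pigs = 3,
                    stationary = c(standing = 0, sitting = 0,
                                   lateral_lying = 1, sternal_lying = 0,
                                   drinking = 0),
                    persistence = 1, seed = 2)
  sim <- simulate_pen(cfg, 40)
  expect_true(all(sim$annotations$class == "lateral_lying"))
  f1 <- sim$annotations[sim$annotations$frame == 1, ]
  for (f in 2:40)
    expect_identical(sim$annotations[sim$annotations$frame == f,
                                     c("x", "y", "width", "height")],
                     f1[, c("x", "y", "width", "height")],
                     ignore_attr = TRUE)
  expect_equal(sim$truth$path_length, rep(0, 3))
})

test_that("behaviours are exclusive and boxes stay inside the pen", {
  sim <- simulate_pen(pen_config(n_pigs = 8, seed = 3), 300)
  ann <- sim$annotations
  expect_false(anyDuplicated(ann[, c("frame", "gt_id")]) > 0)
  expect_true(all(ann$x >= 0 & ann$y >= 0))
  expect_true(all(ann$x + ann$width <= sim$config$width))
  expect_true(all(ann$y + ann$height <= sim$config$height))
  expect_true(all(ann$class %in% behaviour_classes()))
})

test_that("drinking boxes sit at a drinker; lying/sitting pigs are still", {
  cfg <- pen_config(n_pigs = 10, drinker_radius = 60, seed = 4)
  sim <- simulate_pen(cfg, 400)
  ann <- sim$annotations
  drk <- cfg$drinkers
  dr <- ann[ann$class == "drinking", ]
  if (nrow(dr)) {
    cen <- box_centroid(dr)
    if (is.null(dim(cen))) cen <- matrix(cen, 1, 2)
    mind <- vapply(seq_len(nrow(cen)), function(i)
      min(sqrt((drk$cx - cen[i, 1])^2 + (drk$cy - cen[i, 2])^2)), 0)
    expect_true(all(mind <= cfg$drinker_radius + 1e-9))
  }
  # zero displacement across consecutive stationary frames
  for (i in unique(ann$gt_id)) {
    a <- ann[ann$gt_id == i, ]
    a <- a[order(a$frame), ]
    still <- a$class %in% c("sitting", "lateral_lying", "sternal_lying",
                            "drinking")
    run <- which(still[-1] & still[-nrow(a)])
    if (length(run)) {
      dx <- abs((a$x[run + 1] + a$width[run + 1] / 2) -
                  (a$x[run] + a$width[run] / 2))
      expect_true(all(dx < 1e-9))
    }
  }
})

test_that("scripted path length matches the analytics distance to 1e-6", {
  sim <- simulate_pen(pen_config(n_pigs = 4, seed = 6), 150)
  ts <- track_sequence(identity_detector(sim$annotations))
  est <- track_distances_by_pig(ts, sim)
  expect_false(anyNA(est))
  expect_equal(est, sim$truth$path_length, tolerance = 1e-6)
})

test_that("zero-noise degradation is the identity with score 1", {
  sim <- simulate_pen(pen_config(n_pigs = 3, seed = 7), 50)
  dd <- degrade(sim, noise_config())
  expect_equal(nrow(dd$detections), nrow(sim$annotations))
  expect_true(all(dd$detections$score == 1))
  expect_equal(sort(dd$detections$x), sort(sim$annotations$x))
  expect_identical(dd$frames$time, sim$frames$time)
})

test_that("false positives follow the configured Poisson rate", {
  sim <- simulate_pen(pen_config(n_pigs = 1, seed = 8), 1000)
  dd <- degrade(sim, noise_config(miss_rate = 1, fp_rate = 0.5, seed = 9))
  nfp <- nrow(dd$detections)
  expect_lt(abs(nfp - 500), 3 * sqrt(500))
})

test_that("dropped frames keep the survivors' wall-clock timestamps", {
  sim <- simulate_pen(pen_config(n_pigs = 2, seed = 10), 200)
  dd <- degrade(sim, noise_config(frame_drop_rate = 0.3, seed = 11))
  expect_lt(nrow(dd$frames), 200)
  expect_identical(dd$frames$time,
                   sim$frames$time[match(dd$frames$frame, sim$frames$frame)])
  expect_true(all(dd$detections$frame %in% dd$frames$frame))
})

test_that("dwell fractions approach the chain's stationary distribution", {
  # 4-posture world (drinking is spatially gated, so excluded) with short
  # bouts to decorrelate; 3 pigs x 10,000 frames
  pi4 <- c(standing = 0.25, sitting = 0.10, lateral_lying = 0.35,
           sternal_lying = 0.30, drinking = 0)
  cfg <- pen_config(n_pigs = 3, stationary = pi4, persistence = 0.85,
                    seed = 42)
  sim <- simulate_pen(cfg, 10000)
  emp <- colMeans(sim$truth$dwell_fractions)
  expect_true(all(abs(emp - pi4) <= 0.03))
})

test_that("disruption schedule shifts stationary mass and validates", {
  base <- pen_config(n_pigs = 5, seed = 1)
  sched <- feeding_disruption_schedule(base, days = 4, disrupted_days = 3,
                                       effects = c(standing = 0.5))
  expect_length(sched, 4)
  expect_identical(sched[[1]]$stationary, base$stationary)
  expect_lt(sched[[3]]$stationary[["standing"]],
            base$stationary[["standing"]])
  expect_gt(sched[[3]]$stationary[["lateral_lying"]],
            base$stationary[["lateral_lying"]])
  expect_equal(sum(sched[[3]]$stationary), 1)
  # zero effects: all days share the base behaviour budget
  s0 <- feeding_disruption_schedule(base, 2, 2, effects = c(standing = 1))
  expect_identical(s0[[2]]$stationary, base$stationary)
  expect_error(feeding_disruption_schedule(base, 2, 2,
                                           effects = c(flying = 0.5)),
               "unknown class")
  expect_error(feeding_disruption_schedule(
    pen_config(n_pigs = 2, stationary = c(standing = 1, sitting = 0,
                                          lateral_lying = 0,
                                          sternal_lying = 0, drinking = 0)),
    2, 2, effects = c(standing = 0)), "annihilate")
})
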