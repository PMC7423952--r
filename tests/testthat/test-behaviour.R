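test_that("behaviour_index hand examples", {
  expect_equal(behaviour_index(rep(3, 100)), 3)
  expect_equal(behaviour_index(c(2, 0, 1)), 1)
  expect_equal(behaviour_index(rep(0, 10)), 0)
  expect_error(behaviour_index(numeric(0)), "zero recorded frames")
})

random_det <- function(n_frames, n_pigs, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_frames), function(f) {
    k <- sample(0:n_pigs, 1)
    if (k == 0) return(NULL)
    data.frame(frame = f, x = runif(k, 0, 500), y = runif(k, 0, 250),
               width = 40, height = 30,
               class = sample(behaviour_classes(), k, replace = TRUE),
               score = 1)
  }))
}

test_that("one window covering everything reduces to behaviour_index", {
  det <- random_det(40, 5, seed = 1)
  s <- index_series(det, data.frame(window = "all", start = 1, end = 40),
                    frames = 1:40)
  for (cl in behaviour_classes()) {
    counts <- vapply(1:40, function(f)
      sum(det$frame == f & det$class == cl), 0)
    expect_equal(s$index[s$class == cl], behaviour_index(counts))
  }
  # index conservation: sum over classes == mean detections per frame
  expect_equal(sum(s$index), nrow(det) / 40)
})

test_that("frame-weighted mean of split windows equals the global index", {
  det <- random_det(60, 6, seed = 2)
  g <- index_series(det, data.frame(window = "all", start = 1, end = 60),
                    frames = 1:60)
  h <- index_series(det, data.frame(window = c("a", "b"), start = c(1, 31),
                                    end = c(30, 60)), frames = 1:60)
  for (cl in behaviour_classes()) {
    sub <- h[h$class == cl, ]
    expect_equal(sum(sub$index * sub$n_frames) / sum(sub$n_frames),
                 g$index[g$class == cl])
  }
})

test_that("index_series flags empty windows and rejects overlap", {
  det <- random_det(10, 3, seed = 3)
  expect_warning(
    s <- index_series(det, data.frame(window = c("a", "b"), start = c(1, 50),
                                      end = c(10, 60)), frames = 1:10),
    "no recorded frames")
  expect_setequal(unique(s$window), "a")
  expect_error(index_series(det, data.frame(window = c("a", "b"),
                                            start = c(1, 5), end = c(6, 9)),
                            frames = 1:10), "overlap")
})

test_that("percent_change arithmetic and guards", {
  expect_equal(percent_change(1, 2), -50)
  expect_equal(percent_change(2.9, 2), 45)
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_error(percent_change(1, 0), "baseline")
})

test_that("percent_change_table averages baseline windows per class", {
  s <- data.frame(window = rep(c("d1", "d2", "d3"), each = 2),
                  class = rep(c("standing", "sitting"), 3),
                  index = c(2, 1, 4, 1, 1.5, 3), n_frames = 100)
  tab <- percent_change_table(s, c("d1", "d2"), "d3")
  expect_equal(tab$baseline[tab$class == "standing"], 3)
  expect_equal(tab$pct_change[tab$class == "standing"], -50)
  expect_equal(tab$pct_change[tab$class == "sitting"], 200)
  expect_error(percent_change_table(s, "d1", "d1"), "disjoint")
})

fixed_track <- function(frames, cx, cy, cls = "standing",
                        source = "detected") {
  data.frame(frame = frames, x = cx - 20, y = cy - 15, width = 40, height = 30,
             class = cls, score = 1, track_id = 1L, source = source)
}

test_that("build_profile time budgets and worked distances", {
  tr <- rbind(fixed_track(1:80, cx = 100, cy = 100, cls = "standing"),
              fixed_track(81:100, cx = 100, cy = 100, cls = "drinking"))
  p <- build_profile(tr, 1L)
  expect_equal(unname(p$time_budget[c("standing", "drinking")]), c(0.8, 0.2))
  expect_equal(sum(p$time_budget), 1, tolerance = 1e-9)
  expect_equal(p$total_distance, 0)

  # 3-4-5 triangle
  tr2 <- fixed_track(1:2, cx = c(0, 3), cy = c(0, 4))
  expect_equal(build_profile(tr2, 1L)$total_distance, 5)
  expect_equal(total_distance(data.frame(cx = c(0, 3), cy = c(0, 4))), 5)

  # single sample: concentrated budget, zero distance
  p1 <- build_profile(fixed_track(1, 100, 100), 1L)
  expect_equal(unname(p1$time_budget["standing"]), 1)
  expect_equal(p1$total_distance, 0)

  expect_error(build_profile(tr, 99L), "no history")
})

test_that("coasted samples keep the trajectory but not the time budget", {
  tr <- rbind(fixed_track(1:5, cx = 100, cy = 100, cls = "standing"),
              fixed_track(6:10, cx = 100, cy = 100, cls = "standing",
                          source = "coasted"))
  p <- build_profile(tr, 1L)
  expect_equal(nrow(p$samples), 10L)
  expect_equal(unname(p$time_budget["standing"]), 1)  # 5 detected samples only
})

test_that("mean_speed uses wall-clock time so frame drops do not bias it", {
  frames <- 1:100
  set.seed(42)
  keep <- sort(c(1, sample(2:99, 78), 100))   # ~20% dropped, ends kept
  tr <- fixed_track(keep, cx = 2 * keep, cy = 50)
  times <- data.frame(frame = frames, time = (frames - 1) / 25)
  p <- build_profile(tr, 1L, times = times)
  true_speed <- 2 * 25                         # 2 px/frame at 25 fps
  expect_lt(abs(p$mean_speed - true_speed) / true_speed, 0.02)
  expect_equal(mean_speed(data.frame(time = c(0, 4), cx = c(0, 100),
                                     cy = c(0, 0))), 25)
  expect_error(mean_speed(data.frame(time = c(1, 1), cx = c(0, 1),
                                     cy = c(0, 0))), "elapsed")
})

test_that("distance and speed are scale-equivariant", {
  set.seed(8)
  cx <- cumsum(rnorm(20)); cy <- cumsum(rnorm(20))
  s <- data.frame(time = seq(0, by = 0.04, length.out = 20), cx = cx, cy = cy)
  for (sc in c(2, 0.5, 10)) {
    s2 <- transform(s, cx = cx * sc, cy = cy * sc)
    expect_equal(total_distance(s2), sc * total_distance(s))
    expect_equal(mean_speed(s2), sc * mean_speed(s))
  }
})

test_that("profile scale calibration converts to metres", {
  tr <- fixed_track(1:2, cx = c(0, 160), cy = c(50, 50))
  p <- build_profile(tr, 1L, scale = 1 / 160)  # 160 px per metre
  expect_equal(p$total_distance_m, 1)
})
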