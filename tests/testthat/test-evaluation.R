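gt1 <- function(frame = 1, x = 0, y = 0, id = 1L, cls = "standing")
  data.frame(frame = frame, x = x, y = y, width = 10, height = 10,
             class = cls, gt_id = id)
det1 <- function(frame = 1, x = 0, y = 0, score = 1, cls = "standing")
  data.frame(frame = frame, x = x, y = y, width = 10, height = 10,
             class = cls, score = score)

test_that("match_frame basic contracts", {
  gt <- rbind(gt1(x = 0), gt1(x = 40, id = 2L))
  r <- match_frame(rbind(det1(x = 0), det1(x = 40)), gt)
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 0L, 0L))
  r2 <- match_frame(det1()[0, ], gt)
  expect_equal(r2$fn, 2L)
  # one detection overlapping two GT boxes takes the higher-IoU one
  gt3 <- rbind(gt1(x = 0), gt1(x = 4, id = 2L))
  r3 <- match_frame(det1(x = 3), gt3, iou_min = 0.1)
  expect_equal(r3$tp, 1L)
  expect_equal(r3$matches$gt, 2L)      # IoU vs gt2 (7/13) beats gt1 (7/13? no: 0.538 vs 0.412)
  expect_equal(r3$fn, 1L)
  # TP + FN == GT
  expect_equal(r3$tp + r3$fn, nrow(gt3))
})

test_that("average_precision reproduces the 1-GT / 2-detection fixture", {
  gt <- gt1()
  det <- rbind(det1(x = 100, score = 0.9),   # FP, ranked first
               det1(x = 0, score = 0.8))    # TP
  r <- average_precision(det, gt, "standing")
  expect_equal(r$ap, 0.5)
  expect_equal(r$curve$recall, c(0, 1))
  expect_equal(r$curve$precision, c(0, 0.5))
})

test_that("AP is 1 for a perfect detector and invariant to monotone rescaling", {
  gt <- do.call(rbind, lapply(1:5, function(f)
    rbind(gt1(frame = f), gt1(frame = f, x = 40, id = 2L))))
  det <- identity_detector(gt)
  det$score <- seq(0.99, 0.5, length.out = nrow(det))
  r <- average_precision(det, gt, "standing")
  expect_equal(r$ap, 1)
  det2 <- det; det2$score <- det$score^3 / 2     # strictly monotone rescale
  expect_equal(average_precision(det2, gt, "standing")$ap, r$ap)
})

test_that("AP with mixed ranking equals the step-area oracle", {
  # 3 GT; detections ranked TP, FP, TP, FP, TP
  gt <- rbind(gt1(x = 0), gt1(x = 40, id = 2L), gt1(x = 80, id = 3L))
  det <- rbind(det1(x = 0, score = 0.9), det1(x = 200, score = 0.8),
               det1(x = 40, score = 0.7), det1(x = 240, score = 0.6),
               det1(x = 80, score = 0.5))
  r <- average_precision(det, gt, "standing")
  # step areas: (1/3)*1 + (1/3)*(2/3) + (1/3)*(3/5)
  expect_equal(r$ap, 1 / 3 + 2 / 9 + 1 / 5)
})

test_that("mean_average_precision averages present classes only", {
  gt <- rbind(gt1(), gt1(x = 40, id = 2L, cls = "sitting"))
  det <- rbind(det1(score = 0.9),
               det1(x = 100, score = 0.8, cls = "sitting"))
  expect_warning(r <- mean_average_precision(det, gt), "no ground truths")
  expect_equal(sort(names(r$per_class)), c("sitting", "standing"))
  expect_equal(unname(r$map), mean(c(1, 0)))
})

test_that("log-average miss rate endpoints and hand-built fixture", {
  gt <- do.call(rbind, lapply(1:10, function(f) gt1(frame = f)))
  perfect <- identity_detector(gt)
  r <- log_average_miss_rate(perfect, gt, "standing")
  expect_lt(r$lamr, 1e-9)
  nothing <- perfect[0, ]
  expect_equal(log_average_miss_rate(nothing, gt, "standing")$lamr, 1)

  # 8 TPs and 2 FPs with a known score ordering; the 9 log-spaced FPPI
  # reference points pick miss rates {.8 x4, .5 x2, .2 x3} (manual
  # spreadsheet computation)
  det <- rbind(
    do.call(rbind, lapply(1:8, function(f)
      det1(frame = f, score = 1 - 0.05 * f))),
    det1(frame = 1, x = 100, score = 0.88),
    det1(frame = 2, x = 100, score = 0.72))
  r2 <- log_average_miss_rate(det, gt, "standing")
  expect_equal(r2$lamr, exp((4 * log(0.8) + 2 * log(0.5) + 3 * log(0.2)) / 9),
               tolerance = 1e-12)
})

test_that("mot_metrics reproduces the constructed 0.96 fixture", {
  gt <- static_gt(10, 10)                       # GT = 100
  pred <- gt_as_tracks(gt)
  pred <- pred[!(pred$track_id == 1 & pred$frame == 1), ]   # FN
  pred <- pred[!(pred$track_id == 2 & pred$frame == 2), ]   # FN
  pred <- rbind(pred, data.frame(frame = 3, x = 500, y = 200, width = 20,
                                 height = 12, class = "standing", score = 1,
                                 track_id = 99L, source = "detected"))  # FP
  pred$track_id[pred$track_id == 3 & pred$frame >= 6] <- 77L            # IDSW
  mot <- mot_metrics(gt, pred)
  expect_equal(c(mot$fn, mot$fp, mot$idsw), c(2L, 1L, 1L))
  expect_equal(mot$mota, 0.96)
  expect_equal(mot$motp, 1)
})

test_that("swapping two predicted identities mid-sequence counts 2 IDSW", {
  gt <- static_gt(2, 10)
  pred <- gt_as_tracks(gt)
  sw <- pred$frame >= 6
  pred$track_id[sw] <- 3L - pred$track_id[sw]
  mot <- mot_metrics(gt, pred)
  expect_equal(mot$idsw, 2L)
  expect_equal(mot$fn + mot$fp, 0L)
  expect_equal(mot$mota, 1 - 2 / 20)
})

test_that("identical tracks give MOTA 1 and order-free MOTP", {
  gt <- static_gt(5, 8)
  mot <- mot_metrics(gt, gt_as_tracks(gt))
  expect_equal(mot$mota, 1)
  expect_equal(mot$motp, 1)
  expect_equal(motp(c(1, 1 / 7)), (1 + 1 / 7) / 2)
  expect_equal(motp(rev(c(1, 1 / 7))), motp(c(1, 1 / 7)))
  expect_error(motp(numeric(0)), "zero matches")
  # inverse (distance) reading of MOTP
  expect_equal(mot_metrics(gt, gt_as_tracks(gt), inverse_motp = TRUE)$motp, 0)
})

test_that("per-frame matching never yields fewer matches than greedy", {
  set.seed(55)
  for (i in 1:20) {
    ng <- sample(1:5, 1); np <- sample(1:5, 1)
    gt <- data.frame(frame = 1, x = runif(ng, 0, 60), y = runif(ng, 0, 60),
                     width = 20, height = 20, class = "standing",
                     gt_id = seq_len(ng))
    pr <- data.frame(frame = 1, x = runif(np, 0, 60), y = runif(np, 0, 60),
                     width = 20, height = 20, class = "standing", score = 1,
                     track_id = seq_len(np), source = "detected")
    mot <- suppressWarnings(mot_metrics(gt, pr, iou_min = 0.1))
    iou <- box_iou_matrix(gt, pr)
    greedy <- 0L
    used <- logical(np)
    for (g in seq_len(ng)) {
      cand <- which(!used & iou[g, ] >= 0.1)
      if (length(cand)) { used[cand[which.max(iou[g, cand])]] <- TRUE
        greedy <- greedy + 1L }
    }
    expect_gte(mot$tp, greedy)
  }
})

test_that("locomotion_mse arithmetic", {
  expect_equal(locomotion_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(locomotion_mse(c(1, 2), c(2, 2)), 0.5)
  set.seed(66)
  a <- runif(10); b <- runif(10)
  expect_equal(locomotion_mse(a, b), sum((a - b)^2) / 10)
  expect_error(locomotion_mse(1:3, 1:2), "length")
})
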