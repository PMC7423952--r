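#' Match detections to ground truth within one frame
#'
#' Greedy, score-ordered matching for a single class within a single
#' frame: detections are taken in descending score order and each one is
#' matched to the still-unmatched ground-truth box of highest IoU, if that
#' IoU reaches `iou_min`. Unmatched detections are false positives,
#' unmatched ground truths false negatives; every ground truth is matched
#' at most once.
#'
#' @param detections Detections of one frame/class (needs `x, y, width,
#'   height, score`).
#' @param ground_truths Ground-truth boxes of the same frame/class.
#' @param iou_min True-positive IoU threshold (default 0.5).
#' @return List with `tp`, `fp`, `fn`, `matches` (data frame `det, gt,
#'   iou`), and `det_records` (per-detection `score`, `is_tp` in input
#'   order) for curve construction.
#' @export
match_frame <- function(detections, ground_truths, iou_min = 0.5) {
  nd <- nrow(detections); ng <- nrow(ground_truths)
  if (nd == 0L)
    return(list(tp = 0L, fp = 0L, fn = ng,
                matches = data.frame(det = integer(0), gt = integer(0),
                                     iou = numeric(0)),
                det_records = data.frame(score = numeric(0),
                                         is_tp = logical(0))))
  ord <- order(-detections$score)
  is_tp <- logical(nd)
  used <- logical(max(ng, 1L))
  md <- integer(0); mg <- integer(0); mi <- numeric(0)
  if (ng > 0L) {
    iou <- box_iou_matrix(detections, ground_truths)
    for (i in ord) {
      cand <- which(!used[seq_len(ng)] & iou[i, ] >= iou_min)
      if (length(cand)) {
        g <- cand[which.max(iou[i, cand])]
        used[g] <- TRUE
        is_tp[i] <- TRUE
        md <- c(md, i); mg <- c(mg, g); mi <- c(mi, iou[i, g])
      }
    }
  }
  list(tp = sum(is_tp), fp = sum(!is_tp), fn = ng - sum(is_tp),
       matches = data.frame(det = md, gt = mg, iou = mi),
       det_records = data.frame(score = detections$score, is_tp = is_tp))
}

# Score-sorted TP flags for one class across all frames.
class_det_records <- function(detections, ground_truths, class, iou_min) {
  det <- detections[detections$class == class, , drop = FALSE]
  gt <- ground_truths[ground_truths$class == class, , drop = FALSE]
  recs <- list()
  for (f in sort(unique(c(det$frame, gt$frame)))) {
    r <- match_frame(det[det$frame == f, , drop = FALSE],
                     gt[gt$frame == f, , drop = FALSE], iou_min)
    if (nrow(r$det_records)) recs[[length(recs) + 1L]] <- r$det_records
  }
  recs <- if (length(recs)) do.call(rbind, recs) else
    data.frame(score = numeric(0), is_tp = logical(0))
  recs[order(-recs$score), , drop = FALSE]
}

#' Average precision for one behaviour class
#'
#' Area under the precision-recall curve, all-points (step) integration:
#' detections of the class are sorted by descending score across all
#' frames, true/false-positive flags come from the per-frame greedy
#' matching of [match_frame()], and AP is the sum of precision times
#' recall increment at every detection. AP is a rank statistic — any
#' strictly monotone rescaling of the scores leaves it unchanged.
#'
#' @param detections All detections (any classes; filtered internally).
#' @param ground_truths All ground-truth annotations.
#' @param class Behaviour class to evaluate.
#' @param iou_min True-positive IoU threshold (default 0.5).
#' @return List with `ap`, `curve` (data frame `recall, precision`), and
#'   `n_gt`. With zero ground truths of the class, `ap` is `NA` with a
#'   warning.
#' @export
average_precision <- function(detections, ground_truths, class,
                              iou_min = 0.5) {
  n_gt <- sum(ground_truths$class == class)
  if (n_gt == 0L) {
    warning(sprintf("average_precision: no ground truths of class '%s'", class))
    return(list(ap = NA_real_, curve = data.frame(recall = numeric(0),
                                                  precision = numeric(0)),
                n_gt = 0L))
  }
  recs <- class_det_records(detections, ground_truths, class, iou_min)
  if (nrow(recs) == 0L)
    return(list(ap = 0, curve = data.frame(recall = 0, precision = 1),
                n_gt = n_gt))
  tp <- cumsum(recs$is_tp); fp <- cumsum(!recs$is_tp)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  ap <- sum(diff(c(0, recall)) * precision)
  list(ap = ap, curve = data.frame(recall = recall, precision = precision),
       n_gt = n_gt)
}

#' Mean average precision across classes
#'
#' @param detections,ground_truths Full tables.
#' @param classes Classes to include (default the five behaviours);
#'   classes absent from the ground truth are excluded with a warning.
#' @param iou_min True-positive IoU threshold.
#' @return List with `map`, and `per_class` (named AP vector).
#' @export
mean_average_precision <- function(detections, ground_truths,
                                   classes = behaviour_classes(),
                                   iou_min = 0.5) {
  present <- intersect(classes, unique(ground_truths$class))
  skipped <- setdiff(classes, present)
  if (length(skipped))
    warning(sprintf("mean_average_precision: no ground truths for: %s",
                    paste(skipped, collapse = ", ")))
  aps <- vapply(present, function(cl)
    average_precision(detections, ground_truths, cl, iou_min)$ap, 0)
  list(map = mean(aps), per_class = aps)
}

#' Log-average miss rate vs false positives per image
#'
#' The complementary characteristic to the precision-recall curve: as the
#' score threshold sweeps, the miss rate `1 - recall` is traced against
#' FPPI (false positives per image). The scalar summary samples the curve
#' at 9 FPPI reference points log-spaced over `[1e-2, 1]` (for each
#' reference, the miss rate at the largest FPPI not exceeding it; 1.0 if
#' the curve never reaches that low), clips at `1e-10` and takes the
#' geometric mean.
#'
#' @inheritParams average_precision
#' @param n_frames Number of recorded images; defaults to the frames
#'   present in `ground_truths`.
#' @return List with `lamr`, `curve` (data frame `fppi, miss_rate`), and
#'   `n_gt`.
#' @export
log_average_miss_rate <- function(detections, ground_truths, class,
                                  iou_min = 0.5, n_frames = NULL) {
  n_gt <- sum(ground_truths$class == class)
  if (n_gt == 0L) {
    warning(sprintf("log_average_miss_rate: no ground truths of class '%s'",
                    class))
    return(list(lamr = NA_real_,
                curve = data.frame(fppi = numeric(0), miss_rate = numeric(0)),
                n_gt = 0L))
  }
  if (is.null(n_frames)) n_frames <- length(unique(ground_truths$frame))
  recs <- class_det_records(detections, ground_truths, class, iou_min)
  refs <- 10^seq(-2, 0, length.out = 9)
  if (nrow(recs) == 0L) {
    return(list(lamr = 1,
                curve = data.frame(fppi = 0, miss_rate = 1), n_gt = n_gt))
  }
  tp <- cumsum(recs$is_tp); fp <- cumsum(!recs$is_tp)
  fppi <- fp / n_frames
  miss <- 1 - tp / n_gt
  mr_at <- vapply(refs, function(f) {
    ok <- which(fppi <= f)
    if (length(ok)) miss[max(ok)] else 1.0
  }, 0)
  lamr <- exp(mean(log(pmax(mr_at, 1e-10))))
  list(lamr = lamr, curve = data.frame(fppi = fppi, miss_rate = miss),
       n_gt = n_gt)
}

#' CLEAR multi-object tracking metrics: MOTA and MOTP
#'
#' Per frame, ground-truth identities and predicted track identities are
#' matched on IoU at or above `iou_min`. Matching keeps persistence:
#' pairings from the previous frame are retained while still valid, and
#' the remainder is matched optimally (Hungarian, minimising `1 - IoU`).
#' An identity switch (IDSW) is counted whenever a ground-truth animal's
#' matched predicted identity differs from the last identity it was ever
#' matched to. Then
#' `MOTA = 1 - (FN + FP + IDSW) / GT` (sums over frames; at most 1, and 1
#' only with zero errors) and `MOTP` is the mean IoU of all true-positive
#' matches, `sum(d) / sum(c)` — higher is better. Set `inverse_motp` for
#' the `1 - IoU` (lower-better) reading.
#'
#' @param ground_truths Annotations with `gt_id`.
#' @param predicted Track table with `track_id` (e.g.
#'   `track_sequence(...)$tracks`).
#' @param iou_min Match gate (default 0.5).
#' @param inverse_motp Report `1 - IoU` instead of IoU (default `FALSE`).
#' @return A `"mot_report"`: list with `mota`, `motp`, `fn`, `fp`, `idsw`,
#'   `gt_total`, `tp`, `tp_rate`, and `match_ious` (per-frame matched
#'   IoUs).
#' @export
mot_metrics <- function(ground_truths, predicted, iou_min = 0.5,
                        inverse_motp = FALSE) {
  gt_total <- nrow(ground_truths)
  if (gt_total == 0L) stop("mot_metrics: no ground truth")
  pred <- if (inherits(predicted, "track_set")) predicted$tracks else predicted
  frames <- sort(unique(c(ground_truths$frame, pred$frame)))
  fn <- 0L; fp <- 0L; idsw <- 0L; tp <- 0L
  dsum <- 0; csum <- 0L
  last_match <- list()   # gt_id -> last matched track_id
  prev_pairs <- list()   # gt_id -> track_id matched in previous frame
  match_ious <- numeric(0)
  for (f in frames) {
    g <- ground_truths[ground_truths$frame == f, , drop = FALSE]
    p <- pred[pred$frame == f, , drop = FALSE]
    ng <- nrow(g); np <- nrow(p)
    pairs_g <- integer(0); pairs_p <- integer(0); pair_iou <- numeric(0)
    if (ng > 0L && np > 0L) {
      iou <- box_iou_matrix(g, p)
      # persistence: keep previous pairings still valid at this frame
      for (gi in seq_len(ng)) {
        gid <- as.character(g$gt_id[gi])
        tid <- prev_pairs[[gid]]
        if (!is.null(tid)) {
          pj <- match(tid, p$track_id)
          if (!is.na(pj) && iou[gi, pj] >= iou_min) {
            pairs_g <- c(pairs_g, gi); pairs_p <- c(pairs_p, pj)
            pair_iou <- c(pair_iou, iou[gi, pj])
          }
        }
      }
      rem_g <- setdiff(seq_len(ng), pairs_g)
      rem_p <- setdiff(seq_len(np), pairs_p)
      if (length(rem_g) && length(rem_p)) {
        sub <- 1 - iou[rem_g, rem_p, drop = FALSE]
        sub[iou[rem_g, rem_p, drop = FALSE] < iou_min] <- Inf
        sol <- solve_assignment(sub, 1.000001)
        if (nrow(sol$matches)) {
          gi <- rem_g[sol$matches$row]; pj <- rem_p[sol$matches$col]
          pairs_g <- c(pairs_g, gi); pairs_p <- c(pairs_p, pj)
          pair_iou <- c(pair_iou, iou[cbind(gi, pj)])
        }
      }
    }
    nm <- length(pairs_g)
    tp <- tp + nm
    fn <- fn + (ng - nm)
    fp <- fp + (np - nm)
    dsum <- dsum + sum(pair_iou)
    csum <- csum + nm
    match_ious <- c(match_ious, pair_iou)
    new_pairs <- list()
    if (nm) {
      for (k in seq_len(nm)) {
        gid <- as.character(g$gt_id[pairs_g[k]])
        tid <- p$track_id[pairs_p[k]]
        prev <- last_match[[gid]]
        if (!is.null(prev) && prev != tid) idsw <- idsw + 1L
        last_match[[gid]] <- tid
        new_pairs[[gid]] <- tid
      }
    }
    prev_pairs <- new_pairs
  }
  motp <- if (csum > 0) dsum / csum else NA_real_
  if (csum == 0) warning("mot_metrics: no true-positive matches; MOTP undefined")
  if (inverse_motp && !is.na(motp)) motp <- 1 - motp
  structure(list(mota = 1 - (fn + fp + idsw) / gt_total,
                 motp = motp, fn = fn, fp = fp, idsw = idsw,
                 gt_total = gt_total, tp = tp, tp_rate = tp / gt_total,
                 match_ious = match_ious),
            class = "mot_report")
}

#' Multi-object tracking precision from matched overlaps
#'
#' `sum(d) / sum(c)` where `d` are the IoUs of true-positive matches and
#' `c` the number of matches per frame; order of frames is immaterial.
#'
#' @param ious IoU values of all true-positive matches (any order).
#' @return Mean matched IoU in `[0, 1]`.
#' @export
motp <- function(ious) {
  if (length(ious) == 0L) stop("motp: undefined with zero matches")
  sum(ious) / length(ious)
}

#' Locomotion mean squared error
#'
#' Mean of squared differences between true and estimated per-animal
#' locomotion values, reported separately for each metric (total distance
#' travelled, average speed).
#'
#' @param true,estimated Paired numeric vectors (same animal order).
#' @return The MSE.
#' @export
locomotion_mse <- function(true, estimated) {
  if (length(true) != length(estimated))
    stop("locomotion_mse: length mismatch")
  if (length(true) == 0L) stop("locomotion_mse: empty input")
  mean((true - estimated)^2)
}

#' @export
print.mot_report <- function(x, ...) {
  cat(sprintf(
    "MOT report: MOTA %.4f, MOTP %.4f | FN %d FP %d IDSW %d / GT %d (TP rate %.4f)\n",
    x$mota, x$motp, x$fn, x$fp, x$idsw, x$gt_total, x$tp_rate))
  invisible(x)
}
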