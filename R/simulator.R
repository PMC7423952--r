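# Posture-dependent box shapes (width x height, pixels, before the
# per-animal size factor). Lateral lying is elongated, sitting compact;
# drinking resembles standing. Values chosen for a ~160 px/m top-down view
# of finisher pigs in a 640 x 360 px pen.
POSTURE_DIMS <- rbind(standing = c(80, 36),
                      sitting = c(44, 40),
                      lateral_lying = c(90, 48),
                      sternal_lying = c(70, 40),
                      drinking = c(78, 36))

#' Pen simulator configuration
#'
#' The stated world: a 640 x 360 px pen viewed top-down at a nominal
#' 25 fps housing up to 15 pigs with 4 nipple drinkers. Each pig follows a
#' Markov chain over the five behaviours, built as
#' `P = a * I + (1 - a) * 1 pi'` so that `pi` is its stationary
#' distribution and `a` controls bout persistence. Pigs move (a
#' random-heading walk with wall reflection) only while standing; lying
#' and sitting pigs are stationary; drinking can only be entered within
#' `drinker_radius` of a drinker, where the box snaps adjacent to it.
#' Box shape depends on posture (and a fixed per-animal size factor),
#' which gives the anchor clustering something to find.
#'
#' @param width,height Pen size in pixels (defaults 640 x 360).
#' @param fps Nominal frames/second (default 25).
#' @param n_pigs Number of animals (default 15).
#' @param drinkers Data frame `cx, cy` of drinker positions (default 4
#'   along the upper wall); must lie inside the pen.
#' @param drinker_radius Pixels within which drinking may start
#'   (default 15).
#' @param stationary Named stationary distribution over the five
#'   behaviours (must sum to 1). Default: standing 0.20, sitting 0.05,
#'   lateral lying 0.35, sternal lying 0.35, drinking 0.05.
#' @param persistence Diagonal weight `a` of the transition matrix
#'   (default 0.98, i.e. mean bout length 50 frames = 2 s).
#' @param transition Optional explicit 5 x 5 row-stochastic transition
#'   matrix overriding the `stationary`/`persistence` construction.
#' @param speed_range Standing walk speed, pixels/frame (default 1-4).
#' @param size_range Per-animal size factor range (default 0.9-1.1).
#' @param seed World seed.
#' @return A `"pen_config"` list.
#' @export
pen_config <- function(width = 640, height = 360, fps = 25, n_pigs = 15,
                       drinkers = NULL, drinker_radius = 15,
                       stationary = c(standing = 0.20, sitting = 0.05,
                                      lateral_lying = 0.35,
                                      sternal_lying = 0.35, drinking = 0.05),
                       persistence = 0.98, transition = NULL,
                       speed_range = c(1, 4), size_range = c(0.9, 1.1),
                       seed = 1L) {
  cls <- behaviour_classes()
  if (is.null(drinkers))
    drinkers <- data.frame(cx = c(110, 250, 390, 530), cy = rep(62, 4))
  if (n_pigs < 1) stop("pen_config: n_pigs must be >= 1")
  if (any(drinkers$cx < 0 | drinkers$cx > width |
          drinkers$cy < 0 | drinkers$cy > height))
    stop("pen_config: drinkers must lie inside the pen")
  stationary <- stationary[cls]
  if (anyNA(stationary) || abs(sum(stationary) - 1) > 1e-9 ||
      any(stationary < 0))
    stop("pen_config: stationary must be a distribution over the five classes")
  if (is.null(transition)) {
    transition <- persistence * diag(5) +
      (1 - persistence) * matrix(stationary, 5, 5, byrow = TRUE)
    dimnames(transition) <- list(cls, cls)
  } else {
    transition <- as.matrix(transition)
    dimnames(transition) <- list(cls, cls)
  }
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0))
    stop("pen_config: transition rows must be non-negative and sum to 1")
  if (stationary[["drinking"]] > 0 && nrow(drinkers) == 0L)
    stop("pen_config: drinking mass > 0 with zero drinkers")
  structure(list(width = width, height = height, fps = fps, n_pigs = n_pigs,
                 drinkers = drinkers, drinker_radius = drinker_radius,
                 stationary = stationary, persistence = persistence,
                 transition = transition, speed_range = speed_range,
                 size_range = size_range, seed = as.integer(seed)),
            class = "pen_config")
}

#' Detector degradation configuration
#'
#' Emulates the error modes of a bounding-box detector and of farm
#' recording hardware: Gaussian jitter on box corners, missed animals,
#' spurious boxes, confused behaviour classes, and whole dropped frames
#' (survivors keep their wall-clock timestamps). Degradation draws from
#' its own seed, so one simulated world can be degraded at several noise
#' levels for paired comparisons.
#'
#' @param jitter_sigma SD of the Gaussian corner jitter, pixels.
#' @param miss_rate Per-box probability of a missed detection.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param class_confusion Per-box probability of flipping to a random
#'   other class.
#' @param frame_drop_rate Per-frame probability the frame is lost.
#' @param tp_score_min True-positive scores are uniform on
#'   `[tp_score_min, 1]`; the default 1 gives score exactly 1.
#' @param fp_score_range Range of false-positive scores (default
#'   0.1-0.7).
#' @param seed Noise seed (independent of the world seed).
#' @return A `"noise_config"` list.
#' @export
noise_config <- function(jitter_sigma = 0, miss_rate = 0, fp_rate = 0,
                         class_confusion = 0, frame_drop_rate = 0,
                         tp_score_min = 1, fp_score_range = c(0.1, 0.7),
                         seed = 1L) {
  probs <- c(miss_rate, class_confusion, frame_drop_rate)
  if (any(probs < 0 | probs > 1) || jitter_sigma < 0 || fp_rate < 0)
    stop("noise_config: probabilities must be in [0,1], rates non-negative")
  structure(list(jitter_sigma = jitter_sigma, miss_rate = miss_rate,
                 fp_rate = fp_rate, class_confusion = class_confusion,
                 frame_drop_rate = frame_drop_rate,
                 tp_score_min = tp_score_min,
                 fp_score_range = fp_score_range, seed = as.integer(seed)),
            class = "noise_config")
}

#' Simulate a ground-truth pen sequence
#'
#' Generates per-frame annotations (boxes, behaviour classes, stable
#' animal identities), wall-clock timestamps, and the bookkeeping other
#' modules are tested against: each animal's scripted path length and
#' realised per-behaviour dwell fractions. Deterministic per
#' `config$seed`.
#'
#' @param config A [pen_config()].
#' @param n_frames Number of frames to generate.
#' @return A `"pen_sim"`: list with `annotations` (ground-truth table),
#'   `frames` (a [frame_sequence()]), `truth` (list: `path_length`,
#'   `mean_speed`, `dwell_fractions`, `stationary`, `elapsed`), and
#'   `config`.
#' @export
simulate_pen <- function(config, n_frames) {
  stopifnot(inherits(config, "pen_config"), n_frames >= 1)
  cls <- behaviour_classes()
  W <- config$width; H <- config$height; np <- config$n_pigs
  scale_max <- max(config$size_range)
  margin <- max(POSTURE_DIMS) * scale_max / 2 + 1
  lo <- c(margin, margin); hi <- c(W - margin, H - margin)
  drk <- config$drinkers
  clamp <- function(v, a, b) pmin(pmax(v, a), b)

  with_seed(config$seed, {
    size <- stats::runif(np, config$size_range[1], config$size_range[2])
    px <- stats::runif(np, lo[1], hi[1])
    py <- stats::runif(np, lo[2], hi[2])
    heading <- stats::runif(np, 0, 2 * pi)
    speed <- stats::runif(np, config$speed_range[1], config$speed_range[2])
    near_drinker <- function(i) {
      nrow(drk) > 0 &&
        min(sqrt((drk$cx - px[i])^2 + (drk$cy - py[i])^2)) <=
          config$drinker_radius
    }
    beh <- character(np)
    for (i in seq_len(np)) {
      p <- config$stationary
      if (!near_drinker(i)) p["drinking"] <- 0
      beh[i] <- sample(cls, 1, prob = p / sum(p))
    }
    n <- n_frames * np
    ann <- data.frame(frame = integer(n), x = numeric(n), y = numeric(n),
                      width = numeric(n), height = numeric(n),
                      class = character(n), gt_id = integer(n))
    path_len <- numeric(np)
    dwell <- matrix(0L, np, 5, dimnames = list(NULL, cls))
    row <- 0L
    for (f in seq_len(n_frames)) {
      for (i in seq_len(np)) {
        if (f > 1L) {
          p <- config$transition[beh[i], ]
          if (!near_drinker(i)) p["drinking"] <- 0
          nxt <- sample(cls, 1, prob = p / sum(p))
          if (nxt != beh[i]) {
            if (nxt == "standing") {
              heading[i] <- stats::runif(1, 0, 2 * pi)
              speed[i] <- stats::runif(1, config$speed_range[1],
                                       config$speed_range[2])
            } else if (nxt == "drinking") {
              # snap the snout to the nearest drinker
              d2 <- (drk$cx - px[i])^2 + (drk$cy - py[i])^2
              j <- which.min(d2)
              ox <- px[i]; oy <- py[i]
              px[i] <- clamp(drk$cx[j], lo[1], hi[1])
              py[i] <- clamp(drk$cy[j], lo[2], hi[2])
              path_len[i] <- path_len[i] + sqrt((px[i] - ox)^2 + (py[i] - oy)^2)
            }
            beh[i] <- nxt
          }
          if (beh[i] == "standing") {
            heading[i] <- heading[i] + stats::rnorm(1, 0, 0.15)
            nx <- px[i] + speed[i] * cos(heading[i])
            ny <- py[i] + speed[i] * sin(heading[i])
            if (nx < lo[1] || nx > hi[1]) {
              heading[i] <- pi - heading[i]
              nx <- clamp(2 * clamp(nx, lo[1], hi[1]) - nx, lo[1], hi[1])
            }
            if (ny < lo[2] || ny > hi[2]) {
              heading[i] <- -heading[i]
              ny <- clamp(2 * clamp(ny, lo[2], hi[2]) - ny, lo[2], hi[2])
            }
            path_len[i] <- path_len[i] + sqrt((nx - px[i])^2 + (ny - py[i])^2)
            px[i] <- nx; py[i] <- ny
          }
        }
        dims <- POSTURE_DIMS[beh[i], ] * size[i]
        row <- row + 1L
        ann$frame[row] <- f
        ann$x[row] <- px[i] - dims[1] / 2
        ann$y[row] <- py[i] - dims[2] / 2
        ann$width[row] <- dims[1]
        ann$height[row] <- dims[2]
        ann$class[row] <- beh[i]
        ann$gt_id[row] <- i
        dwell[i, beh[i]] <- dwell[i, beh[i]] + 1L
      }
    }
    frames <- frame_sequence(seq_len(n_frames), fps = config$fps,
                             time = (seq_len(n_frames) - 1) / config$fps)
    elapsed <- (n_frames - 1) / config$fps
    truth <- list(path_length = path_len,
                  mean_speed = if (elapsed > 0) path_len / elapsed else
                    rep(NA_real_, np),
                  dwell_fractions = dwell / n_frames,
                  stationary = config$stationary, elapsed = elapsed)
    structure(list(annotations = ann, frames = frames, truth = truth,
                   config = config, n_frames = n_frames),
              class = "pen_sim")
  })
}

#' Degrade ground truth into noisy detections
#'
#' The reference implementation of the detector contract's noisy channel:
#' applies [noise_config()] degradation to a simulated sequence. With all
#' noise parameters zero the detections equal the annotations with score
#' exactly 1.
#'
#' @param sim A [simulate_pen()] result.
#' @param noise A [noise_config()].
#' @return List with `detections` (validated table) and `frames` (the
#'   surviving [frame_sequence()], timestamps unchanged).
#' @export
degrade <- function(sim, noise = noise_config()) {
  stopifnot(inherits(sim, "pen_sim"), inherits(noise, "noise_config"))
  ann <- sim$annotations
  frames <- sim$frames
  W <- sim$config$width; H <- sim$config$height
  cls <- behaviour_classes()
  with_seed(noise$seed, {
    keep_frame <- stats::runif(nrow(frames)) >= noise$frame_drop_rate
    kept <- frames$frame[keep_frame]
    frames_out <- frames[keep_frame, , drop = FALSE]
    ann <- ann[ann$frame %in% kept, , drop = FALSE]
    nb <- nrow(ann)
    detected <- stats::runif(nb) >= noise$miss_rate
    det <- ann[detected, , drop = FALSE]
    nd <- nrow(det)
    if (nd > 0L) {
      if (noise$jitter_sigma > 0) {
        x1 <- det$x + stats::rnorm(nd, 0, noise$jitter_sigma)
        y1 <- det$y + stats::rnorm(nd, 0, noise$jitter_sigma)
        x2 <- det$x + det$width + stats::rnorm(nd, 0, noise$jitter_sigma)
        y2 <- det$y + det$height + stats::rnorm(nd, 0, noise$jitter_sigma)
        x1 <- pmin(pmax(x1, 0), W - 1); y1 <- pmin(pmax(y1, 0), H - 1)
        x2 <- pmin(pmax(x2, x1 + 1), W); y2 <- pmin(pmax(y2, y1 + 1), H)
        det$x <- x1; det$y <- y1
        det$width <- x2 - x1; det$height <- y2 - y1
      }
      if (noise$class_confusion > 0) {
        flip <- stats::runif(nd) < noise$class_confusion
        for (r in which(flip))
          det$class[r] <- sample(setdiff(cls, det$class[r]), 1)
      }
      score <- if (noise$tp_score_min >= 1) rep(1, nd) else
        stats::runif(nd, noise$tp_score_min, 1)
    } else score <- numeric(0)
    out <- data.frame(frame = det$frame, x = det$x, y = det$y,
                      width = det$width, height = det$height,
                      class = det$class, score = score)
    if (noise$fp_rate > 0 && length(kept)) {
      nfp <- stats::rpois(length(kept), noise$fp_rate)
      total <- sum(nfp)
      if (total > 0L) {
        fr <- rep(kept, nfp)
        dims <- POSTURE_DIMS[sample(nrow(POSTURE_DIMS), total, replace = TRUE), ,
                             drop = FALSE] * stats::runif(total, 0.8, 1.2)
        cx <- stats::runif(total, dims[, 1] / 2, W - dims[, 1] / 2)
        cy <- stats::runif(total, dims[, 2] / 2, H - dims[, 2] / 2)
        fps_df <- data.frame(frame = fr, x = cx - dims[, 1] / 2,
                             y = cy - dims[, 2] / 2,
                             width = dims[, 1], height = dims[, 2],
                             class = sample(cls, total, replace = TRUE),
                             score = stats::runif(total,
                                                  noise$fp_score_range[1],
                                                  noise$fp_score_range[2]))
        out <- rbind(out, fps_df)
      }
    }
    out <- out[order(out$frame, -out$score), , drop = FALSE]
    rownames(out) <- NULL
    list(detections = out, frames = frames_out)
  })
}

#' Multi-day schedule with feeding-disruption effects
#'
#' Builds one [pen_config()] per day; on disrupted days the stationary
#' behaviour mass is shifted multiplicatively (e.g. standing x 0.5) and
#' renormalised, emulating the behavioural signature of food restriction
#' (less standing, more lateral lying). Used to demonstrate that the
#' baseline percent-change analysis recovers the direction of an injected
#' disruption.
#'
#' @param pen Base [pen_config()].
#' @param days Total number of days.
#' @param disrupted_days Integer day indices receiving the effect.
#' @param effects Named multiplicative factors on stationary mass, e.g.
#'   `c(standing = 0.5)`; unnamed classes absorb the freed mass through
#'   renormalisation.
#' @return List of length `days` of `pen_config` objects (seeds offset by
#'   day so days are independent worlds).
#' @export
feeding_disruption_schedule <- function(pen, days, disrupted_days,
                                        effects = c(standing = 0.5)) {
  stopifnot(inherits(pen, "pen_config"), days >= 1)
  if (any(effects < 0)) stop("feeding_disruption_schedule: negative effect")
  bad <- setdiff(names(effects), behaviour_classes())
  if (length(bad))
    stop(sprintf("feeding_disruption_schedule: unknown class '%s'", bad[1]))
  pi_d <- pen$stationary
  pi_d[names(effects)] <- pi_d[names(effects)] * effects
  if (sum(pi_d) <= 0)
    stop("feeding_disruption_schedule: effects annihilate all behaviour mass")
  pi_d <- pi_d / sum(pi_d)
  lapply(seq_len(days), function(d) {
    pen_config(width = pen$width, height = pen$height, fps = pen$fps,
               n_pigs = pen$n_pigs, drinkers = pen$drinkers,
               drinker_radius = pen$drinker_radius,
               stationary = if (d %in% disrupted_days) pi_d else pen$stationary,
               persistence = pen$persistence,
               speed_range = pen$speed_range, size_range = pen$size_range,
               seed = pen$seed + d)
  })
}

#' @export
print.pen_sim <- function(x, ...) {
  cat(sprintf("Pen simulation: %d pigs, %d frames (%.1f s at %g fps), seed %d\n",
              x$config$n_pigs, x$n_frames, x$truth$elapsed, x$config$fps,
              x$config$seed))
  invisible(x)
}
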