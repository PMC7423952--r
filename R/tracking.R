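#' Tracker configuration
#'
#' Parameters of the tracking-by-detection scheme: IoU gating and
#' non-assignment cost for the Munkres/Hungarian association, the
#' tentative-to-confirmed lifecycle thresholds, and the Kalman noise
#' scales of the constant-velocity centroid model.
#'
#' @param gate_iou_min Minimum IoU between a track's predicted box and a
#'   detection for the pair to be assignable (default 0.3).
#' @param cost_of_non_assignment Penalty for leaving a track or detection
#'   unassigned (default 0.7); costs are `1 - IoU`.
#' @param confirm_hits Consecutive assigned frames required to promote a
#'   tentative track to confirmed (default 3).
#' @param max_coast Maximum consecutive missed (coasted) frames a
#'   confirmed track survives before deletion (default 10). Coasting
#'   counts recorded frames, not wall-clock, since dropped frames are
#'   simply absent from the stream.
#' @param process_noise,measurement_noise Kalman noise scales
#'   (pixels^2; defaults 0.01 and 1).
#' @return A `"tracker_config"` list.
#' @export
tracker_config <- function(gate_iou_min = 0.3, cost_of_non_assignment = 0.7,
                           confirm_hits = 3L, max_coast = 10L,
                           process_noise = 0.01, measurement_noise = 1) {
  stopifnot(gate_iou_min >= 0, gate_iou_min < 1, confirm_hits >= 1,
            max_coast >= 0, process_noise >= 0, measurement_noise > 0)
  structure(list(gate_iou_min = gate_iou_min,
                 cost_of_non_assignment = cost_of_non_assignment,
                 confirm_hits = as.integer(confirm_hits),
                 max_coast = as.integer(max_coast),
                 process_noise = process_noise,
                 measurement_noise = measurement_noise),
            class = "tracker_config")
}

# Predicted box of a live track: constant-velocity centroid prediction,
# extents carried from the last assigned detection.
track_predicted_box <- function(tr) {
  kf <- kf_predict(tr$kf)
  c(x = kf$x[1] - tr$shape[1] / 2, y = kf$x[2] - tr$shape[2] / 2,
    width = tr$shape[1], height = tr$shape[2])
}

#' Fresh tracker state
#'
#' @param config A [tracker_config()].
#' @return Opaque tracker state consumed and returned by [tracker_step()].
#' @export
tracker_state <- function(config = tracker_config()) {
  list(config = config, tracks = list(), next_id = 1L,
       events = list(), archive = list(), last_frame = -Inf)
}

new_track <- function(id, frame, det, config) {
  cen <- c(det$x + det$width / 2, det$y + det$height / 2)
  list(id = id, status = "tentative",
       kf = kf_init(cen[1], cen[2], q = config$process_noise,
                    r = config$measurement_noise),
       shape = c(det$width, det$height), cls = det$class,
       hits = 1L, misses = 0L, ever_confirmed = FALSE,
       history = list(list(frame = frame, x = det$x, y = det$y,
                           width = det$width, height = det$height,
                           class = det$class, score = det$score,
                           source = "detected")))
}

#' Advance the tracker by one recorded frame
#'
#' Implements the per-frame association cycle: predict every live track
#' with its Kalman filter, build the gated `1 - IoU` cost matrix against
#' the frame's detections, solve the assignment (Munkres/Hungarian with a
#' cost of non-assignment), then apply the lifecycle rules — assigned
#' tracks are Kalman-updated and take the detection's behaviour class;
#' unassigned detections start new tentative tracks; unassigned confirmed
#' tracks coast on the prediction (class carried, flagged `coasted`);
#' tentative tracks are deleted on their first miss (they may stem from a
#' false detection); confirmed tracks die after `max_coast` consecutive
#' misses; tentative tracks reaching `confirm_hits` consecutive hits are
#' confirmed.
#'
#' @param state Tracker state from [tracker_state()] or a previous step.
#' @param detections Detections of this frame (rows with `frame ==
#'   frame_index`; may be empty).
#' @param frame_index Recorded frame index; must exceed the previous
#'   step's index.
#' @return Updated state.
#' @export
tracker_step <- function(state, detections, frame_index) {
  if (frame_index <= state$last_frame)
    stop(sprintf("tracker_step: out-of-order frame index %s", frame_index))
  cfg <- state$config
  det <- detections
  if (nrow(det) && any(det$frame != frame_index))
    stop("tracker_step: detections carry a different frame index")
  nt <- length(state$tracks); nd <- nrow(det)

  preds <- NULL
  if (nt > 0) {
    preds <- t(vapply(state$tracks, track_predicted_box, numeric(4)))
    for (i in seq_len(nt)) state$tracks[[i]]$kf <- kf_predict(state$tracks[[i]]$kf)
  }

  if (nt > 0 && nd > 0) {
    iou <- box_iou_matrix(preds, det)
    cost <- 1 - iou
    cost[iou < cfg$gate_iou_min] <- Inf
    sol <- solve_assignment(cost, cfg$cost_of_non_assignment)
  } else {
    sol <- list(matches = data.frame(row = integer(0), col = integer(0)),
                unmatched_rows = seq_len(nt), unmatched_cols = seq_len(nd))
  }

  log_event <- function(id, ev) {
    state$events[[length(state$events) + 1L]] <<-
      list(frame = frame_index, track_id = id, event = ev)
  }

  # assigned tracks: measurement update, lifecycle hit
  for (r in seq_len(nrow(sol$matches))) {
    i <- sol$matches$row[r]; j <- sol$matches$col[r]
    d <- det[j, ]
    tr <- state$tracks[[i]]
    tr$kf <- kf_update(tr$kf, c(d$x + d$width / 2, d$y + d$height / 2))
    tr$shape <- c(d$width, d$height)
    tr$cls <- d$class
    tr$hits <- tr$hits + 1L
    tr$misses <- 0L
    tr$history[[length(tr$history) + 1L]] <-
      list(frame = frame_index, x = d$x, y = d$y, width = d$width,
           height = d$height, class = d$class, score = d$score,
           source = "detected")
    if (tr$status == "tentative" && tr$hits >= cfg$confirm_hits) {
      tr$status <- "confirmed"
      tr$ever_confirmed <- TRUE
      log_event(tr$id, "confirmed")
    }
    state$tracks[[i]] <- tr
  }

  # unassigned tracks: tentative die, confirmed coast or die
  drop_idx <- integer(0)
  for (i in sol$unmatched_rows) {
    tr <- state$tracks[[i]]
    tr$misses <- tr$misses + 1L
    tr$hits <- 0L
    if (tr$status == "tentative") {
      log_event(tr$id, "deleted_tentative")
      drop_idx <- c(drop_idx, i)
    } else if (tr$misses > cfg$max_coast) {
      log_event(tr$id, "deleted_lost")
      tr$status <- "deleted"
      state$archive[[length(state$archive) + 1L]] <- tr
      drop_idx <- c(drop_idx, i)
    } else {
      pb <- c(x = tr$kf$x[1] - tr$shape[1] / 2,
              y = tr$kf$x[2] - tr$shape[2] / 2,
              width = tr$shape[1], height = tr$shape[2])
      tr$history[[length(tr$history) + 1L]] <-
        list(frame = frame_index, x = unname(pb[1]), y = unname(pb[2]),
             width = unname(pb[3]), height = unname(pb[4]),
             class = tr$cls, score = NA_real_, source = "coasted")
      state$tracks[[i]] <- tr
      next
    }
    state$tracks[[i]] <- tr
  }
  if (length(drop_idx)) state$tracks <- state$tracks[-drop_idx]

  # unassigned detections: spawn tentative tracks (confirm immediately if M == 1)
  for (j in sol$unmatched_cols) {
    tr <- new_track(state$next_id, frame_index, det[j, ], cfg)
    log_event(tr$id, "initialised")
    if (cfg$confirm_hits <= 1L) {
      tr$status <- "confirmed"; tr$ever_confirmed <- TRUE
      log_event(tr$id, "confirmed")
    }
    state$tracks[[length(state$tracks) + 1L]] <- tr
    state$next_id <- state$next_id + 1L
  }

  state$last_frame <- frame_index
  state
}

track_to_rows <- function(tr) {
  h <- tr$history
  data.frame(frame = vapply(h, `[[`, 0, "frame"),
             x = vapply(h, `[[`, 0, "x"),
             y = vapply(h, `[[`, 0, "y"),
             width = vapply(h, `[[`, 0, "width"),
             height = vapply(h, `[[`, 0, "height"),
             class = vapply(h, `[[`, "", "class"),
             score = vapply(h, `[[`, 0, "score"),
             track_id = tr$id,
             source = vapply(h, `[[`, "", "source"))
}

#' Track a full detection sequence
#'
#' Folds [tracker_step()] over the recorded frames (in increasing order;
#' gaps are allowed and count as single steps) and extracts the valid
#' tracks — those that were confirmed at some point. Their histories
#' include the tentative prefix, so a pig detected from its first frame
#' contributes a full-length trajectory. Deterministic: no randomness is
#' involved anywhere in the tracker.
#'
#' @param detections Validated detections table (all frames).
#' @param config A [tracker_config()].
#' @param frames Optional frame vector or [frame_sequence()] giving the
#'   recorded frames to step over (defaults to the frames present in
#'   `detections`); frames with no detections still advance coasting.
#' @return A `"track_set"`: list with `tracks` (data frame
#'   `frame,x,y,width,height,class,score,track_id,source`), `events`
#'   (lifecycle audit log), and `config`.
#' @export
track_sequence <- function(detections, config = tracker_config(),
                           frames = NULL) {
  if (nrow(detections)) validate_detections(detections)
  if (is.null(frames)) {
    frames <- sort(unique(detections$frame))
  } else if (is.data.frame(frames)) {
    frames <- frames$frame
  }
  st <- tracker_state(config)
  for (f in frames) {
    st <- tracker_step(st, detections[detections$frame == f, , drop = FALSE], f)
  }
  finished <- c(st$archive, st$tracks)
  keep <- Filter(function(tr) isTRUE(tr$ever_confirmed), finished)
  tracks <- if (length(keep)) do.call(rbind, lapply(keep, track_to_rows)) else
    data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
               width = numeric(0), height = numeric(0), class = character(0),
               score = numeric(0), track_id = integer(0), source = character(0))
  tracks <- tracks[order(tracks$frame, tracks$track_id), , drop = FALSE]
  rownames(tracks) <- NULL
  events <- if (length(st$events)) {
    data.frame(frame = vapply(st$events, `[[`, 0, "frame"),
               track_id = vapply(st$events, `[[`, 0L, "track_id"),
               event = vapply(st$events, `[[`, "", "event"))
  } else data.frame(frame = integer(0), track_id = integer(0),
                    event = character(0))
  structure(list(tracks = tracks, events = events, config = config),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  ids <- unique(x$tracks$track_id)
  cat(sprintf("Track set: %d valid track(s), %d frame rows, %d lifecycle events\n",
              length(ids), nrow(x$tracks), nrow(x$events)))
  invisible(x)
}
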