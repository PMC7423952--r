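#' Group-level behaviour index
#'
#' The behaviour index BH of a video segment is the mean number of animals
#' exhibiting the behaviour per recorded frame: the per-frame counts summed
#' over the segment's N recorded frames, divided by N. Because N counts
#' recorded frames only, the index is comparable across segments with
#' different amounts of dropped frames.
#'
#' @param counts Per-frame counts of animals showing the behaviour (one
#'   element per recorded frame).
#' @return The index, a non-negative scalar.
#' @examples
#' behaviour_index(c(2, 0, 1))  # 1
#' @export
behaviour_index <- function(counts) {
  if (length(counts) == 0L)
    stop("behaviour_index: undefined for zero recorded frames")
  sum(counts) / length(counts)
}

# Per-frame, per-class detection counts over an explicit recorded-frame set.
frame_class_counts <- function(detections, frames, classes = behaviour_classes()) {
  tab <- table(factor(detections$frame, levels = frames),
               factor(detections$class, levels = classes))
  matrix(tab, nrow = length(frames), ncol = length(classes),
         dimnames = list(NULL, classes))
}

#' Behaviour indices per observation window
#'
#' Applies [behaviour_index()] per window and per behaviour class, counting
#' frame-wise from detections — group-level scoring needs no tracking.
#' Windows with zero recorded frames are flagged and omitted.
#'
#' @param detections Detections (or annotations relabelled as detections)
#'   table.
#' @param windows Data frame with columns `window` (label), `start`, `end`
#'   (inclusive frame-index range); windows must not overlap.
#' @param frames Recorded frame indices (vector or [frame_sequence()]);
#'   defaults to the frames present in `detections`, but pass the true
#'   recorded set whenever frames can be empty of detections.
#' @param classes Class vocabulary (default the five behaviours).
#' @return Data frame `window, class, index, n_frames` of class
#'   `"behaviour_index_series"`.
#' @export
index_series <- function(detections, windows, frames = NULL,
                         classes = behaviour_classes()) {
  stopifnot_cols(windows, c("window", "start", "end"), "windows")
  o <- order(windows$start)
  if (any(windows$start[o][-1] <= windows$end[o][-nrow(windows)]))
    stop("index_series: windows overlap")
  if (is.null(frames)) frames <- sort(unique(detections$frame))
  if (is.data.frame(frames)) frames <- frames$frame
  out <- list()
  for (r in seq_len(nrow(windows))) {
    w <- windows[r, ]
    fr <- frames[frames >= w$start & frames <= w$end]
    if (length(fr) == 0L) {
      warning(sprintf("index_series: window '%s' has no recorded frames; omitted",
                      w$window))
      next
    }
    det <- detections[detections$frame %in% fr, , drop = FALSE]
    cnt <- frame_class_counts(det, fr, classes)
    out[[length(out) + 1L]] <-
      data.frame(window = w$window, class = classes,
                 index = colSums(cnt) / length(fr), n_frames = length(fr))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(window = character(0), class = character(0),
               index = numeric(0), n_frames = integer(0))
  rownames(res) <- NULL
  structure(res, class = c("behaviour_index_series", "data.frame"))
}

#' Percent change of an index against a baseline
#'
#' `100 * (index - baseline) / baseline`, signed: a halved standing index
#' reports -50.
#'
#' @param index Index value(s) in the comparison window.
#' @param baseline Baseline index; must be strictly positive.
#' @return Signed percent change.
#' @export
percent_change <- function(index, baseline) {
  if (any(baseline <= 0))
    stop("percent_change: baseline must be > 0")
  100 * (index - baseline) / baseline
}

#' Baseline / comparison percent-change table
#'
#' For each behaviour class, averages the index over the baseline windows
#' and reports the signed percent change of every comparison window
#' against that baseline. `mode = "pre_days"` takes the windows
#' immediately preceding the comparison period as baseline;
#' `mode = "pre_and_post_mean"` additionally includes post-period windows
#' (the caller supplies both sets in `baseline_windows`).
#'
#' @param series A [index_series()] result.
#' @param baseline_windows Window labels forming the baseline.
#' @param comparison_windows Window labels to compare (must be disjoint
#'   from the baseline).
#' @param mode Baseline framing, recorded in the output for provenance.
#' @return Data frame `class, window, baseline, index, pct_change`.
#' @export
percent_change_table <- function(series, baseline_windows, comparison_windows,
                                 mode = c("pre_days", "pre_and_post_mean")) {
  mode <- match.arg(mode)
  if (length(intersect(baseline_windows, comparison_windows)))
    stop("percent_change_table: baseline and comparison windows must be disjoint")
  out <- list()
  for (cl in unique(series$class)) {
    s <- series[series$class == cl, , drop = FALSE]
    base <- mean(s$index[s$window %in% baseline_windows])
    for (w in comparison_windows) {
      idx <- s$index[s$window == w]
      if (length(idx) == 0L) next
      pc <- if (base > 0) percent_change(idx, base) else NA_real_
      out[[length(out) + 1L]] <-
        data.frame(class = cl, window = w, baseline = base, index = idx,
                   pct_change = pc, mode = mode)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Individual animal profile from a track
#'
#' Builds the per-animal profile the tracker enables: the time-stamped
#' centroid trajectory with the behaviour at each point, the time budget
#' (fraction of detected samples per behaviour), the total distance
#' travelled (Euclidean centroid path length) and the mean speed. Coasted
#' (Kalman-only) samples keep the trajectory continuous but are excluded
#' from the time budget, which counts detected behaviours only.
#'
#' @param track_set A [track_sequence()] result (or its `tracks` data
#'   frame).
#' @param vid Track identity (vID) to profile.
#' @param times Frame timestamps: a [frame_sequence()] or data frame with
#'   `frame`, `time` columns; defaults to `frame / fps` at `fps = 25`.
#' @param scale Optional metres/pixel calibration; when given, distance
#'   and speed are additionally reported in metres and m/s.
#' @param fps Nominal fps used when `times` is absent.
#' @return An `"individual_profile"`: list with `vid`, `samples` (data
#'   frame `time, cx, cy, behaviour, source`), `time_budget` (named
#'   proportions over the five classes), `total_distance`, `mean_speed`,
#'   and optional `total_distance_m`, `mean_speed_m`.
#' @export
build_profile <- function(track_set, vid, times = NULL, scale = NULL,
                          fps = 25) {
  tracks <- if (inherits(track_set, "track_set")) track_set$tracks else track_set
  tr <- tracks[tracks$track_id == vid, , drop = FALSE]
  if (nrow(tr) == 0L)
    stop(sprintf("build_profile: no history for vID %s", vid))
  tr <- tr[order(tr$frame), , drop = FALSE]
  if (is.null(times)) {
    tm <- tr$frame / fps
  } else {
    if (is.data.frame(times)) {
      tm <- times$time[match(tr$frame, times$frame)]
    } else tm <- times[match(tr$frame, sort(unique(tr$frame)))]
    if (anyNA(tm)) stop("build_profile: missing timestamp for some frames")
  }
  cen <- box_centroid(tr)
  if (is.null(dim(cen))) cen <- matrix(cen, 1, 2)
  samples <- data.frame(time = tm, cx = cen[, 1], cy = cen[, 2],
                        behaviour = tr$class, source = tr$source)
  detected <- samples$behaviour[samples$source == "detected"]
  if (length(detected)) {
    tb <- table(factor(detected, levels = behaviour_classes()))
    time_budget <- as.numeric(tb) / length(detected)
  } else time_budget <- rep(NA_real_, 5)
  names(time_budget) <- behaviour_classes()
  dist <- path_length(samples$cx, samples$cy)
  elapsed <- samples$time[nrow(samples)] - samples$time[1]
  prof <- list(vid = vid, samples = samples, time_budget = time_budget,
               total_distance = dist,
               mean_speed = if (elapsed > 0) dist / elapsed else NA_real_)
  if (!is.null(scale)) {
    prof$total_distance_m <- dist * scale
    prof$mean_speed_m <- prof$mean_speed * scale
  }
  structure(prof, class = "individual_profile")
}

path_length <- function(cx, cy) {
  n <- length(cx)
  if (n < 2L) return(0)
  sum(sqrt(diff(cx)^2 + diff(cy)^2))
}

#' Total distance travelled
#'
#' Sum over consecutive trajectory samples of the Euclidean distance
#' between centroids.
#'
#' @param profile An [build_profile()] result, or a data frame with
#'   `cx`, `cy` columns.
#' @return Distance in pixels (or the profile's calibrated unit).
#' @export
total_distance <- function(profile) {
  s <- if (inherits(profile, "individual_profile")) profile$samples else profile
  path_length(s$cx, s$cy)
}

#' Mean speed
#'
#' Total distance divided by elapsed wall-clock time between the first and
#' last sample. True timestamps are used, so dropped frames do not inflate
#' the estimate.
#'
#' @inheritParams total_distance
#' @return Speed in pixels/second.
#' @export
mean_speed <- function(profile) {
  s <- if (inherits(profile, "individual_profile")) profile$samples else profile
  elapsed <- s$time[nrow(s)] - s$time[1]
  if (is.na(elapsed) || elapsed <= 0)
    stop("mean_speed: undefined for zero elapsed time")
  path_length(s$cx, s$cy) / elapsed
}

#' @export
print.individual_profile <- function(x, ...) {
  cat(sprintf("Profile vID %s: %d samples, distance %.1f px, speed %.2f px/s\n",
              x$vid, nrow(x$samples), x$total_distance, x$mean_speed))
  tb <- x$time_budget
  cat("  time budget:",
      paste(sprintf("%s %.2f", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}
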