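#' Behaviour class vocabulary
#'
#' The five mutually exclusive behaviours scored per pig per frame:
#' standing, sitting, lateral lying, sternal lying, drinking. Pens whose
#' drinkers fall outside the camera field of view use the 4-class subset
#' without `drinking`.
#'
#' @param drinking Include the `drinking` class (default `TRUE`).
#' @return Character vector of class names.
#' @export
behaviour_classes <- function(drinking = TRUE) {
  cls <- c("standing", "sitting", "lateral_lying", "sternal_lying", "drinking")
  if (drinking) cls else cls[1:4]
}

DETECTION_COLS <- c("frame", "x", "y", "width", "height", "class", "score")
ANNOTATION_COLS <- c("frame", "x", "y", "width", "height", "class", "gt_id")

validate_boxes_df <- function(df, what) {
  bad <- which(!(df$width > 0 & df$height > 0))
  if (length(bad))
    stop(sprintf("%s: non-positive box extent at row %d", what, bad[1]))
  bad <- which(!(df$frame >= 0 & df$frame == floor(df$frame)))
  if (length(bad))
    stop(sprintf("%s: invalid frame index at row %d", what, bad[1]))
  bad <- which(!(df$class %in% behaviour_classes()))
  if (length(bad))
    stop(sprintf("%s: unknown class '%s' at row %d", what,
                 df$class[bad[1]], bad[1]))
  invisible(df)
}

#' Validate a detections table
#'
#' @param df Data frame with columns
#'   `frame, x, y, width, height, class, score` (optionally `track_id`,
#'   `source`).
#' @return The input, invisibly, sorted by frame then score (descending);
#'   errors name the first offending row.
#' @export
validate_detections <- function(df) {
  stopifnot_cols(df, DETECTION_COLS, "detections")
  validate_boxes_df(df, "detections")
  bad <- which(!(df$score >= 0 & df$score <= 1))
  if (length(bad))
    stop(sprintf("detections: score outside [0,1] at row %d", bad[1]))
  invisible(df[order(df$frame, -df$score), , drop = FALSE])
}

#' Validate an annotations (ground-truth) table
#'
#' @param df Data frame with columns
#'   `frame, x, y, width, height, class, gt_id`.
#' @return The input, invisibly, sorted by frame then `gt_id`.
#' @export
validate_annotations <- function(df) {
  stopifnot_cols(df, ANNOTATION_COLS, "annotations")
  validate_boxes_df(df, "annotations")
  dup <- df[!is.na(df$gt_id), c("frame", "gt_id")]
  if (anyDuplicated(dup))
    stop("annotations: duplicated gt_id within a frame")
  invisible(df[order(df$frame, df$gt_id), , drop = FALSE])
}

# CSV writer with full-precision numerics and a schema header comment, so
# read -> write -> read is an identity on all fields.
write_schema_csv <- function(df, path, schema) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num))
    out[[j]] <- trimws(formatC(df[[j]], format = "g", digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pentrack %s v1", schema), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_schema_csv <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("%s: parse error in %s: %s",
                                     what, path, conditionMessage(e))))
  df
}

#' Read / write per-frame detections
#'
#' The wire format is CSV with header
#' `frame,x,y,width,height,class,score[,track_id,source]`, one row per
#' detection, preceded by a `# pentrack detections v1` schema comment.
#' Numeric fields are serialised at full precision so a write/read
#' round-trip preserves them bit-exactly. Malformed rows, unknown class
#' strings and out-of-range scores are rejected with the offending row
#' named.
#'
#' @param path File path.
#' @return `read_detections()`: a validated, frame-sorted data frame.
#' @export
read_detections <- function(path) {
  df <- read_schema_csv(path, "detections")
  if (nrow(df) == 0L) {
    df <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                     width = numeric(0), height = numeric(0),
                     class = character(0), score = numeric(0))
    return(df)
  }
  validate_detections(df)
  df[order(df$frame, -df$score), , drop = FALSE]
}

#' @rdname read_detections
#' @param df Detections data frame (see [validate_detections()]).
#' @export
write_detections <- function(df, path) {
  validate_detections(df)
  write_schema_csv(df, path, "detections")
}

#' Read / write ground-truth annotations
#'
#' Same wire format as detections but with a `gt_id` column carrying the
#' stable per-animal identity instead of a confidence score.
#'
#' @param path File path.
#' @return `read_annotations()`: a validated, frame-sorted data frame.
#' @export
read_annotations <- function(path) {
  df <- read_schema_csv(path, "annotations")
  if (nrow(df) == 0L) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      width = numeric(0), height = numeric(0),
                      class = character(0), gt_id = integer(0)))
  }
  validate_annotations(df)
  df[order(df$frame, df$gt_id), , drop = FALSE]
}

#' @rdname read_annotations
#' @param df Annotations data frame (see [validate_annotations()]).
#' @export
write_annotations <- function(df, path) {
  validate_annotations(df)
  write_schema_csv(df, path, "annotations")
}

#' Frame sequence with wall-clock timestamps
#'
#' Recording hardware under farm conditions often drops frames, so frame
#' indices may have gaps while surviving frames keep their true wall-clock
#' spacing. Timestamps are carried separately from detections so locomotion
#' speed uses elapsed time, not frame counts.
#'
#' @param frames Strictly increasing integer frame indices.
#' @param fps Nominal frames/second used to derive timestamps when `time`
#'   is not given.
#' @param time Optional explicit non-decreasing timestamps (seconds).
#' @return Data frame with columns `frame`, `time`; attribute `fps`.
#' @export
frame_sequence <- function(frames, fps = 25, time = NULL) {
  frames <- as.integer(frames)
  if (is.unsorted(frames, strictly = TRUE))
    stop("frame_sequence: frame indices must be strictly increasing")
  if (is.null(time)) time <- frames / fps
  if (length(time) != length(frames) || is.unsorted(time))
    stop("frame_sequence: timestamps must be non-decreasing, one per frame")
  structure(data.frame(frame = frames, time = time), fps = fps,
            class = c("frame_sequence", "data.frame"))
}

#' Identity detector: the reference implementation of the detector contract
#'
#' Any function `f(annotations)` returning a valid detections table plugs
#' into the pipeline; this one reproduces the ground truth with confidence
#' 1.0 and is the noise-free reference. The simulator's degradation channel
#' ([degrade()]) is the noisy reference implementation.
#'
#' @param annotations Ground-truth annotations table.
#' @return Detections data frame (score 1.0; empty frames yield zero rows,
#'   never an error).
#' @export
identity_detector <- function(annotations) {
  if (nrow(annotations) == 0L)
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      width = numeric(0), height = numeric(0),
                      class = character(0), score = numeric(0)))
  validate_annotations(annotations)
  data.frame(frame = annotations$frame, x = annotations$x, y = annotations$y,
             width = annotations$width, height = annotations$height,
             class = annotations$class, score = 1.0)
}
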