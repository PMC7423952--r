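#' Axis-aligned bounding box
#'
#' Boxes follow the `[x y width height]` convention: `(x, y)` is the
#' upper-left corner in image coordinates (origin at the image's upper-left,
#' y growing downward, 0-based), and the box covers the continuous region
#' `[x, x + width] x [y, y + height]`. Sub-pixel coordinates are allowed.
#'
#' @param x,y Upper-left corner, in pixels.
#' @param width,height Box extents, in pixels; must be strictly positive.
#' @return A named numeric vector `c(x, y, width, height)` of class `"bbox"`.
#' @examples
#' b <- bbox(3, 5, 4, 2)
#' box_centroid(b)  # (5, 6)
#' @export
bbox <- function(x, y, width, height) {
  v <- c(x = as.numeric(x), y = as.numeric(y),
         width = as.numeric(width), height = as.numeric(height))
  if (anyNA(v) || any(!is.finite(v)))
    stop("bbox: coordinates must be finite")
  if (v[["width"]] <= 0 || v[["height"]] <= 0)
    stop("bbox: width and height must be strictly positive")
  class(v) <- "bbox"
  v
}

# Coerce a bbox / length-4 vector / data.frame rows to an n x 4 matrix
# with columns x, y, width, height.
as_box_matrix <- function(b) {
  if (is.data.frame(b)) {
    m <- as.matrix(b[, c("x", "y", "width", "height"), drop = FALSE])
  } else if (is.matrix(b)) {
    m <- b[, 1:4, drop = FALSE]
  } else {
    m <- matrix(as.numeric(b), ncol = 4, byrow = TRUE)
  }
  colnames(m) <- c("x", "y", "width", "height")
  if (any(m[, "width"] <= 0) || any(m[, "height"] <= 0))
    stop("invalid box: non-positive extent")
  m
}

#' Intersection-over-union of two boxes
#'
#' Overlap area divided by union area, computed on continuous coordinates.
#' Boxes that merely touch along an edge have intersection area 0 and hence
#' IoU 0. Vectorised: `a` and `b` may be single boxes or equal-length sets.
#'
#' @param a,b Boxes as [bbox()] vectors, n x 4 matrices or data frames with
#'   columns `x, y, width, height`.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' box_iou(bbox(0, 0, 2, 2), bbox(1, 1, 2, 2))  # 1/7
#' @export
box_iou <- function(a, b) {
  A <- as_box_matrix(a); B <- as_box_matrix(b)
  ix <- pmax(0, pmin(A[, 1] + A[, 3], B[, 1] + B[, 3]) - pmax(A[, 1], B[, 1]))
  iy <- pmax(0, pmin(A[, 2] + A[, 4], B[, 2] + B[, 4]) - pmax(A[, 2], B[, 2]))
  inter <- ix * iy
  union <- A[, 3] * A[, 4] + B[, 3] * B[, 4] - inter
  unname(inter / union)
}

#' Cross IoU matrix between two box sets
#'
#' @param a,b Box sets (n x 4 and m x 4; any form accepted by [box_iou()]).
#' @return An n x m matrix with `[i, j] = box_iou(a_i, b_j)`.
#' @export
box_iou_matrix <- function(a, b) {
  A <- as_box_matrix(a); B <- as_box_matrix(b)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
  ix <- pmax(0, outer(A[, 1] + A[, 3], B[, 1] + B[, 3], pmin) -
               outer(A[, 1], B[, 1], pmax))
  iy <- pmax(0, outer(A[, 2] + A[, 4], B[, 2] + B[, 4], pmin) -
               outer(A[, 2], B[, 2], pmax))
  inter <- ix * iy
  union <- outer(A[, 3] * A[, 4], B[, 3] * B[, 4], `+`) - inter
  inter / union
}

#' Box centroid
#'
#' Centre point where the box diagonals intersect:
#' `(x + width/2, y + height/2)`.
#'
#' @param b A box or box set.
#' @return For a single box, a named vector `c(cx, cy)`; for a set, an
#'   n x 2 matrix.
#' @export
box_centroid <- function(b) {
  m <- as_box_matrix(b)
  out <- cbind(cx = m[, 1] + m[, 3] / 2, cy = m[, 2] + m[, 4] / 2)
  if (nrow(out) == 1L) c(cx = out[1, 1], cy = out[1, 2]) else out
}

# Coerce shapes ((w,h) pair, n x 2 matrix, or data.frame) to an n x 2 matrix.
as_shape_matrix <- function(s) {
  if (is.data.frame(s)) {
    m <- as.matrix(s[, c("width", "height"), drop = FALSE])
  } else if (is.matrix(s)) {
    m <- s[, 1:2, drop = FALSE]
  } else {
    m <- matrix(as.numeric(s), ncol = 2, byrow = TRUE)
  }
  colnames(m) <- c("width", "height")
  if (any(m <= 0)) stop("invalid shape: non-positive extent")
  m
}

#' Shape (position-free) IoU
#'
#' IoU of two boxes co-aligned at a common upper-left corner, so only the
#' extents matter. This is the similarity used for anchor-box clustering,
#' where anchors encode shape/scale priors without a location.
#'
#' @param a,b Shapes as `(width, height)` pairs, n x 2 matrices, or data
#'   frames with `width`/`height` columns. Vectorised with recycling of a
#'   single shape against a set.
#' @return Numeric vector of values in `[0, 1]`.
#' @examples
#' shape_iou(c(2, 2), c(4, 4))  # 0.25
#' shape_iou(c(1, 4), c(4, 1))  # 1/7
#' @export
shape_iou <- function(a, b) {
  A <- as_shape_matrix(a); B <- as_shape_matrix(b)
  if (nrow(A) == 1L && nrow(B) > 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
  if (nrow(B) == 1L && nrow(A) > 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
  inter <- pmin(A[, 1], B[, 1]) * pmin(A[, 2], B[, 2])
  union <- A[, 1] * A[, 2] + B[, 1] * B[, 2] - inter
  unname(inter / union)
}

#' Shape distance for anchor clustering
#'
#' `1 - shape_iou(a, b)`. Symmetric and in `[0, 1]`; note 1 - IoU is not a
#' metric in general (the triangle inequality may fail), which K-medoids
#' tolerates.
#'
#' @inheritParams shape_iou
#' @return Numeric vector of distances in `[0, 1]`.
#' @export
shape_distance <- function(a, b) 1 - shape_iou(a, b)

# Full pairwise shape-distance matrix (n x n), vectorised.
shape_distance_matrix <- function(shapes) {
  S <- as_shape_matrix(shapes)
  inter <- outer(S[, 1], S[, 1], pmin) * outer(S[, 2], S[, 2], pmin)
  area <- S[, 1] * S[, 2]
  1 - inter / (outer(area, area, `+`) - inter)
}
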