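#' Anchor-box estimation by K-medoids clustering of box shapes
#'
#' Clusters training-box shapes `(width, height)` with the shape-IoU
#' distance `1 - shape_iou` and returns the `k` medoid shapes as anchor
#' boxes. Medoids are actual members of the training set, which makes the
#' anchors robust to outlier boxes (unlike a mean-based centre).
#'
#' The optimiser is PAM-style: a seeded greedy farthest-point
#' initialisation ("k-medoids++" flavour) followed by swap descent until no
#' single medoid/non-medoid swap lowers the total distance, repeated for
#' `restarts` independent starts; the best run (lowest total distance, ties
#' broken by lexicographic anchor order) is returned. Duplicate shapes are
#' collapsed to weighted unique shapes internally, which leaves the optimum
#' unchanged.
#'
#' @param boxes Training boxes: anything accepted by [shape_iou()] (an
#'   n x 2 matrix of shapes, or a data frame with `width`/`height` columns,
#'   e.g. annotations from [read_annotations()]).
#' @param k Number of anchors; must not exceed the number of distinct
#'   shapes.
#' @param seed Integer seed; results are deterministic for fixed
#'   `(boxes, k, seed, restarts)`.
#' @param restarts Number of independent restarts (default 20).
#' @param warm_start Optional shapes (m x 2) injected as one extra
#'   initialisation candidate; used by [anchor_sweep()] to make the
#'   quality curve monotone in `k`.
#' @return An object of class `"anchor_set"`: list with `k`, `anchors`
#'   (k x 2 matrix, lexicographically ordered), `mean_iou` (the quality
#'   measure, see [mean_iou_quality()]), `total_distance`, `seed`,
#'   `restarts`.
#' @examples
#' shapes <- rbind(matrix(10, 10, 2), matrix(40, 10, 2))
#' kmedoids_anchors(shapes, k = 2, seed = 1)$anchors
#' @export
kmedoids_anchors <- function(boxes, k, seed = 1L, restarts = 20L,
                             warm_start = NULL) {
  S <- as_shape_matrix(boxes)
  if (nrow(S) == 0L) stop("kmedoids_anchors: empty box list")
  if (k < 1L) stop("kmedoids_anchors: k must be >= 1")
  key <- paste(S[, 1], S[, 2], sep = "x")
  uniq <- !duplicated(key)
  U <- S[uniq, , drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[uniq])))
  nu <- nrow(U)
  if (k > nu)
    stop(sprintf("kmedoids_anchors: k = %d exceeds %d distinct shapes", k, nu))
  # order unique shapes lexicographically for deterministic tie-breaking
  o <- order(U[, 1], U[, 2])
  U <- U[o, , drop = FALSE]; w <- w[o]
  D <- shape_distance_matrix(U)

  total_cost <- function(med) sum(w * apply(D[med, , drop = FALSE], 2, min))

  pam_run <- function(init) {
    med <- sort(unique(init))
    repeat {
      cur <- total_cost(med)
      best <- list(cost = cur, med = med)
      non <- setdiff(seq_len(nu), med)
      if (!length(non)) break
      for (i in seq_along(med)) {
        rest <- med[-i]
        if (length(rest)) {
          drest <- if (length(rest) == 1L) D[rest, ] else
            apply(D[rest, , drop = FALSE], 2, min)
        } else drest <- rep(Inf, nu)
        # candidate totals for replacing med[i] by each non-medoid, vectorised
        cand_cost <- colSums(t(pmin(D[non, , drop = FALSE],
                                    matrix(drest, length(non), nu,
                                           byrow = TRUE))) * w)
        j <- which.min(cand_cost)
        if (length(j) && cand_cost[j] < best$cost - 1e-12) {
          best <- list(cost = cand_cost[j], med = sort(c(rest, non[j])))
        }
      }
      if (best$cost >= cur - 1e-12) break
      med <- best$med
    }
    list(med = med, cost = total_cost(med))
  }

  greedy_init <- function(first) {
    med <- first
    while (length(med) < k) {
      dmin <- apply(D[med, , drop = FALSE], 2, min)
      dmin[med] <- -Inf
      med <- c(med, which.max(dmin))  # which.max: lowest index on ties
    }
    med
  }

  inits <- with_seed(seed, {
    firsts <- sample.int(nu, size = restarts, replace = restarts > nu, prob = w)
    lapply(firsts, greedy_init)
  })
  if (!is.null(warm_start)) {
    Wm <- as_shape_matrix(warm_start)
    idx <- match(paste(Wm[, 1], Wm[, 2], sep = "x"), paste(U[, 1], U[, 2], sep = "x"))
    idx <- unique(idx[!is.na(idx)])
    if (length(idx) > k) idx <- idx[seq_len(k)]
    if (length(idx) >= 1L) inits <- c(inits, list(greedy_init(idx)))
  }

  best <- NULL
  for (init in inits) {
    run <- pam_run(init)
    if (is.null(best) || run$cost < best$cost - 1e-12 ||
        (abs(run$cost - best$cost) <= 1e-12 &&
         !identical(run$med, best$med) &&
         paste(run$med, collapse = ",") < paste(best$med, collapse = ","))) {
      best <- run
    }
  }
  anchors <- U[best$med, , drop = FALSE]
  anchors <- anchors[order(anchors[, 1], anchors[, 2]), , drop = FALSE]
  rownames(anchors) <- NULL
  structure(list(k = as.integer(k), anchors = anchors,
                 mean_iou = mean_iou_quality(anchors, S),
                 total_distance = best$cost,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "anchor_set")
}

#' Mean-IoU quality of an anchor set
#'
#' Mean, over all training boxes, of the best shape IoU achieved by any
#' anchor. Larger is better: 1 means every box shape is itself an anchor.
#' The mean is box-weighted (each training box counts once, regardless of
#' cluster sizes).
#'
#' @param anchors An `"anchor_set"` or a k x 2 matrix of shapes.
#' @param boxes Training boxes/shapes.
#' @return A scalar in `[0, 1]`.
#' @export
mean_iou_quality <- function(anchors, boxes) {
  A <- if (inherits(anchors, "anchor_set")) anchors$anchors else
    as_shape_matrix(anchors)
  if (nrow(A) == 0L) stop("mean_iou_quality: empty anchor set")
  S <- as_shape_matrix(boxes)
  if (nrow(S) == 0L) stop("mean_iou_quality: empty box list")
  best <- rep(0, nrow(S))
  for (i in seq_len(nrow(A)))
    best <- pmax(best, shape_iou(A[i, , drop = FALSE], S))
  mean(best)
}

#' Anchor-count / quality trade-off sweep
#'
#' Runs [kmedoids_anchors()] for `k = 1..k_max` and records the mean-IoU
#' quality of each solution. Each `k` receives the previous solution's
#' medoids as a warm-start candidate, which guarantees a non-decreasing
#' quality curve.
#'
#' @inheritParams kmedoids_anchors
#' @param k_max Largest anchor count to try (clipped to the number of
#'   distinct shapes).
#' @return An object of class `"anchor_sweep"`: data frame with columns
#'   `k` and `mean_iou`, plus attribute `anchor_sets` (list of the fitted
#'   `"anchor_set"` objects).
#' @export
anchor_sweep <- function(boxes, k_max = 15L, seed = 1L, restarts = 20L) {
  if (k_max < 1L) stop("anchor_sweep: k_max must be >= 1")
  S <- as_shape_matrix(boxes)
  ndistinct <- nrow(unique(S))
  ks <- seq_len(min(k_max, ndistinct))
  sets <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    sets[[i]] <- kmedoids_anchors(S, ks[i], seed = seed + i - 1L,
                                  restarts = restarts, warm_start = prev)
    prev <- sets[[i]]$anchors
  }
  out <- data.frame(k = ks, mean_iou = vapply(sets, `[[`, 0, "mean_iou"))
  structure(out, class = c("anchor_sweep", "data.frame"), anchor_sets = sets)
}

#' Shape scatter for box-distribution inspection
#'
#' Per-box `(aspect_ratio, area)` pairs, the coordinates used to visualise
#' the training-box distribution that anchor clustering summarises.
#'
#' @param boxes Boxes or shapes.
#' @return Data frame with columns `aspect_ratio` (`width / height`) and
#'   `area` (`width * height`); zero rows for empty input.
#' @export
shape_scatter <- function(boxes) {
  if ((is.data.frame(boxes) || is.matrix(boxes)) && nrow(boxes) == 0L)
    return(data.frame(aspect_ratio = numeric(0), area = numeric(0)))
  if (is.null(dim(boxes)) && length(boxes) == 0L)
    return(data.frame(aspect_ratio = numeric(0), area = numeric(0)))
  S <- as_shape_matrix(boxes)
  data.frame(aspect_ratio = unname(S[, 1] / S[, 2]),
             area = unname(S[, 1] * S[, 2]), row.names = NULL)
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set: k = %d, mean IoU = %.4f (seed %d, %d restarts)\n",
              x$k, x$mean_iou, x$seed, x$restarts))
  a <- x$anchors
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %2d: %g x %g\n", i, a[i, 1], a[i, 2]))
  invisible(x)
}
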