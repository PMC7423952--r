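# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: IoU by counting unit grid cells, assignment by
# exhaustive enumeration, K-medoids by enumerating all medoid subsets.

# Grid-rasterisation IoU for integer-coordinate boxes: a box (x,y,w,h)
# covers unit cells (x..x+w-1) x (y..y+h-1).
grid_iou <- function(a, b) {
  cells <- function(bx) {
    g <- expand.grid(x = seq(bx[1], bx[1] + bx[3] - 1),
                     y = seq(bx[2], bx[2] + bx[4] - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(unique(c(ca, cb)))
}

# Exhaustive assignment optimum with per-row/column non-assignment cost.
# Enumerates every injective partial assignment, vectorised over the
# option grid (0 = leave row unassigned).
brute_assignment_cost <- function(cost, cna) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return((n + m) * cna)
  grid <- as.matrix(expand.grid(rep(list(0:m), n)))
  dup <- rep(FALSE, nrow(grid))
  if (n > 1L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      dup <- dup | (grid[, i] > 0 & grid[, i] == grid[, j])
  }
  grid <- grid[!dup, , drop = FALSE]
  tot <- rep(0, nrow(grid))
  for (i in seq_len(n)) tot <- tot + c(cna, cost[i, ])[grid[, i] + 1L]
  tot <- tot + (m - rowSums(grid > 0)) * cna
  min(tot)
}

# Closed-form shape distance, written independently of the package.
shape_dist_oracle <- function(a, b) {
  inter <- min(a[1], b[1]) * min(a[2], b[2])
  1 - inter / (a[1] * a[2] + b[1] * b[2] - inter)
}

# Exhaustive K-medoids optimum: minimum, over all k-subsets of distinct
# shapes, of the total distance from every box to its nearest medoid.
exhaustive_medoid_cost <- function(shapes, k) {
  shapes <- matrix(as.numeric(shapes), ncol = 2)
  u <- unique(shapes)
  D <- matrix(0, nrow(u), nrow(shapes))
  for (i in seq_len(nrow(u)))
    for (j in seq_len(nrow(shapes)))
      D[i, j] <- shape_dist_oracle(u[i, ], shapes[j, ])
  sets <- utils::combn(nrow(u), k)
  best <- Inf
  for (c in seq_len(ncol(sets))) {
    tot <- sum(apply(D[sets[, c], , drop = FALSE], 2, min))
    best <- min(best, tot)
  }
  best
}

# Static multi-animal ground truth: `n` well-separated boxes repeated over
# `frames` frames, identity i at a fixed location.
static_gt <- function(n, frames, cls = "standing") {
  do.call(rbind, lapply(seq_len(frames), function(f)
    data.frame(frame = f, x = 40 * seq_len(n), y = 10, width = 20,
               height = 12, class = cls, gt_id = seq_len(n))))
}

gt_as_tracks <- function(gt) {
  data.frame(frame = gt$frame, x = gt$x, y = gt$y, width = gt$width,
             height = gt$height, class = gt$class, score = 1,
             track_id = gt$gt_id, source = "detected")
}

# Map each valid track to the ground-truth pig whose first-frame centroid
# is nearest; returns the estimated total distance per pig (NA if a pig
# has no track).
track_distances_by_pig <- function(track_set, sim) {
  est <- rep(NA_real_, sim$config$n_pigs)
  f1 <- sim$annotations[sim$annotations$frame == 1, ]
  for (v in sort(unique(track_set$tracks$track_id))) {
    tr <- track_set$tracks[track_set$tracks$track_id == v, ]
    c1 <- box_centroid(tr[1, ])
    gt <- which.min((f1$x + f1$width / 2 - c1[1])^2 +
                      (f1$y + f1$height / 2 - c1[2])^2)
    est[gt] <- build_profile(track_set, v, times = sim$frames)$total_distance
  }
  est
}
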