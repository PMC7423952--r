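# Large finite stand-in for forbidden (gated) assignments; kept finite so
# the potentials in the Hungarian solver stay well defined.
FORBIDDEN_COST <- 1e9

# O(n^3) Hungarian algorithm (Jonker-Volgenant style shortest augmenting
# paths with dual potentials) on a square cost matrix. Returns the column
# assigned to each row.
hungarian_square <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  # 1-based with a dummy column 0 stored at index 1
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j+1]: row currently assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      cr <- cost[i0, ] - u[i0 + 1L] - v[2:(n + 1)]
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          if (cr[j] < minv[j + 1L]) {
            minv[j + 1L] <- cr[j]
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      idx <- which(used)
      u[p[idx] + 1L] <- u[p[idx] + 1L] + delta
      v[idx] <- v[idx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Minimum-cost assignment with a cost of non-assignment
#'
#' Solves the rectangular assignment problem used for detection-to-track
#' association: each row (track) and column (detection) may be left
#' unassigned at cost `cost_of_non_assignment`, and forbidden (gated)
#' entries are never matched. The Munkres/Hungarian solution is globally
#' optimal: the total of matched costs plus non-assignment penalties is
#' minimal.
#'
#' Internally the n x m problem is padded to an (n + m) square matrix
#' whose diagonal dummy blocks carry the non-assignment cost, then solved
#' by an O(N^3) shortest-augmenting-path Hungarian algorithm.
#'
#' @param cost Numeric n x m matrix; use `Inf` (or `NA`) for forbidden
#'   pairs. Empty matrices are allowed.
#' @param cost_of_non_assignment Penalty charged once for each unmatched
#'   row and each unmatched column.
#' @return List with `matches` (data frame `row`, `col`, `cost`),
#'   `unmatched_rows`, `unmatched_cols`, and `total_cost`.
#' @examples
#' solve_assignment(rbind(c(0.1, 0.9), c(0.8, 0.2)), 1.0)$matches
#' @export
solve_assignment <- function(cost, cost_of_non_assignment) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  empty <- list(matches = data.frame(row = integer(0), col = integer(0),
                                     cost = numeric(0)),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m),
                total_cost = (n + m) * cost_of_non_assignment)
  if (n == 0L || m == 0L) return(empty)
  C <- cost
  C[!is.finite(C)] <- FORBIDDEN_COST
  N <- n + m
  big <- matrix(FORBIDDEN_COST, N, N)
  big[seq_len(n), seq_len(m)] <- C
  big[seq_len(n), m + seq_len(n)] <-
    FORBIDDEN_COST * (1 - diag(n)) + cost_of_non_assignment * diag(n)
  big[n + seq_len(m), seq_len(m)] <-
    FORBIDDEN_COST * (1 - diag(m)) + cost_of_non_assignment * diag(m)
  big[n + seq_len(m), m + seq_len(n)] <- 0
  a <- hungarian_square(big)
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(n)) {
    j <- a[i]
    if (j <= m && C[i, j] < FORBIDDEN_COST / 2) {
      rows <- c(rows, i); cols <- c(cols, j)
    }
  }
  matches <- data.frame(row = rows, col = cols,
                        cost = if (length(rows)) cost[cbind(rows, cols)]
                        else numeric(0))
  un_r <- setdiff(seq_len(n), rows)
  un_c <- setdiff(seq_len(m), cols)
  list(matches = matches, unmatched_rows = un_r, unmatched_cols = un_c,
       total_cost = sum(matches$cost) +
         (length(un_r) + length(un_c)) * cost_of_non_assignment)
}
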