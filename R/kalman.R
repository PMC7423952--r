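# Constant-velocity Kalman filter on the box centroid.
# State: (cx, cy, vx, vy) in pixels and pixels/frame-step; measurement:
# the assigned detection's centroid. Box extents are not filtered — the
# last assigned detection's shape is carried alongside the state.

kf_matrices <- function(q, r) {
  F <- diag(4); F[1, 3] <- 1; F[2, 4] <- 1
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  # white-acceleration process noise (discrete, dt = 1 frame-step)
  G <- c(0.5, 0.5, 1, 1)
  Q <- q * diag(c(0.25, 0.25, 1, 1))
  Q[1, 3] <- Q[3, 1] <- q * 0.5
  Q[2, 4] <- Q[4, 2] <- q * 0.5
  R <- r * diag(2)
  list(F = F, H = H, Q = Q, R = R)
}

kf_init <- function(cx, cy, q = 0.01, r = 1, p0_pos = 10, p0_vel = 100) {
  m <- kf_matrices(q, r)
  list(x = c(cx, cy, 0, 0),
       P = diag(c(p0_pos, p0_pos, p0_vel, p0_vel)),
       F = m$F, H = m$H, Q = m$Q, R = m$R)
}

kf_predict <- function(kf) {
  kf$x <- as.vector(kf$F %*% kf$x)
  kf$P <- kf$F %*% kf$P %*% t(kf$F) + kf$Q
  kf$P <- (kf$P + t(kf$P)) / 2   # keep covariance symmetric
  kf
}

kf_update <- function(kf, z) {
  y <- z - as.vector(kf$H %*% kf$x)
  S <- kf$H %*% kf$P %*% t(kf$H) + kf$R
  K <- kf$P %*% t(kf$H) %*% solve(S)
  kf$x <- kf$x + as.vector(K %*% y)
  I_KH <- diag(4) - K %*% kf$H
  # Joseph form for numerical PSD preservation
  kf$P <- I_KH %*% kf$P %*% t(I_KH) + K %*% kf$R %*% t(K)
  kf$P <- (kf$P + t(kf$P)) / 2
  kf
}
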