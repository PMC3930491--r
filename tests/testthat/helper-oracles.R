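# Independent oracles used across the test files. They re-derive the
# quantities from first principles (projection differencing, scalar
# loops) and deliberately share no code with the implementation paths
# they check.

# Central-difference projection oracle for the first-order flow: project
# every dot at t - dt and t + dt with a locally written pin-hole
# projection and difference the image positions.
fd_flow_oracle <- function(scene, traj, camera, frame, dt = 1e-4) {
  project <- function(st) {
    psi <- st$yaw
    R <- cbind(c(cos(psi), 0, -sin(psi)), c(0, 1, 0),
               c(sin(psi), 0, cos(psi)))
    V <- sweep(scene$dots, 2, st$P) %*% R
    f <- camera$focal_length
    list(x = f * V[, 1] / V[, 3], y = f * V[, 2] / V[, 3], z = V[, 3])
  }
  t0 <- traj$t[frame]
  p0 <- project(trajectory_state(traj, t0))
  pm <- project(trajectory_state(traj, t0 - dt))
  pp <- project(trajectory_state(traj, t0 + dt))
  u <- (pp$x - pm$x) / (2 * dt)
  v <- (pp$y - pm$y) / (2 * dt)
  list(x = p0$x, y = p0$y, u = u, v = v, z = p0$z)
}

# Matches oracle samples to computed flow samples by image position and
# returns the maximum relative flow error.
fd_flow_max_rel_error <- function(scene, traj, camera, frame, dt = 1e-4) {
  fl <- compute_flow(scene, traj, camera, frame)
  or <- fd_flow_oracle(scene, traj, camera, frame, dt)
  idx <- match(round(fl$x, 10), round(or$x, 10))
  stopifnot(!anyNA(idx))
  num <- sqrt((fl$u - or$u[idx])^2 + (fl$v - or$v[idx])^2)
  den <- pmax(sqrt(or$u[idx]^2 + or$v[idx]^2), 1e-6)
  max(num / den)
}

# Scalar double-loop template match (no vectorization, no shared helpers).
brute_match_oracle <- function(flow, template, sigma_d, camera) {
  sd_iu <- camera$focal_length * tan(0) + camera$focal_length *
    (sigma_d * pi / 180)
  total <- 0
  n <- flow$n_visible
  for (i in seq_len(n)) {
    fx <- flow$u[i]; fy <- flow$v[i]
    nrm <- sqrt(fx^2 + fy^2)
    if (nrm <= 1e-12) next
    dx <- flow$x[i] - template$com[1]
    dy <- flow$y[i] - template$com[2]
    rho <- sqrt(dx^2 + dy^2)
    if (rho <= 1e-12) next
    rx <- dx / rho; ry <- dy / rho
    tx <- cos(template$phi) * rx - sin(template$phi) * ry
    ty <- cos(template$phi) * ry + sin(template$phi) * rx
    total <- total + exp(-rho / sd_iu) * (fx * tx + fy * ty) / nrm
  }
  total / n
}

# Scalar double-loop Gaussian pooling.
brute_pool_oracle <- function(flow, sigma_deg, radius_deg, camera) {
  s <- camera$focal_length * sigma_deg * pi / 180
  r <- camera$focal_length * radius_deg * pi / 180
  n <- flow$n_visible
  u <- numeric(n); v <- numeric(n)
  for (i in seq_len(n)) {
    wsum <- 0; usum <- 0; vsum <- 0
    for (j in seq_len(n)) {
      d2 <- (flow$x[i] - flow$x[j])^2 + (flow$y[i] - flow$y[j])^2
      if (d2 > r^2) next
      w <- exp(-d2 / (2 * s^2))
      wsum <- wsum + w
      usum <- usum + w * flow$u[j]
      vsum <- vsum + w * flow$v[j]
    }
    u[i] <- usum / wsum
    v[i] <- vsum / wsum
  }
  list(u = u, v = v)
}

# Minimal hand-made flow field.
toy_flow <- function(x, y, u, v, frame = 1L, f = 1) {
  structure(list(frame = frame, x = x, y = y, u = u, v = v,
                 n_visible = length(x), focal_length = f),
            class = "mst_flow")
}

# A small bank for dynamics tests (fast to integrate).
toy_bank <- function(n_pattern = 5, n_x = 3, n_y = 1) {
  build_template_bank(camera_model(), n_pattern = n_pattern, n_x = n_x,
                      n_y = n_y)
}

# Hand-built activity object with a prescribed final activation vector.
toy_activity <- function(bank, z_final) {
  structure(list(z = matrix(z_final, ncol = 1), bank = bank),
            class = "mst_activity")
}
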