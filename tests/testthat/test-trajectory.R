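test_that("circular trajectories keep speed r*omega tangent to the circle", {
  r <- 15; omega <- 0.12
  tr <- make_circular_trajectory(r, 1, omega, "gaze_along_heading")
  speeds <- sqrt(rowSums(tr$T^2))
  expect_equal(speeds, rep(r * omega, tr$frames), tolerance = 1e-12)
  expect_true(all(tr$T[, 2] == 0))  # motion parallel to the ground
  # positions lie on a circle of radius r
  ctr <- c(-r, 0)  # lambda = +1 circle center in (X, Z)
  d <- sqrt((tr$P[, 1] - ctr[1])^2 + (tr$P[, 3] - ctr[2])^2)
  expect_equal(d, rep(r, tr$frames), tolerance = 1e-9)
})

test_that("the quarter-circle traversal guard raises", {
  expect_error(make_circular_trajectory(2, 1, 2, frames = 60,
                                        frame_rate = 60),
               "quarter circle")
  expect_silent(make_circular_trajectory(2, 1, 1.5, frames = 60,
                                         frame_rate = 60))
})

test_that("gaze conditions set the camera rotation they describe", {
  r <- 15; omega <- 0.1
  tz <- make_circular_trajectory(r, 1, omega, "z_axis")
  expect_true(all(tz$yaw == 0) && all(tz$yaw_rate == 0))
  th <- make_circular_trajectory(r, 1, omega, "gaze_along_heading")
  expect_equal(th$yaw, -omega * th$t, tolerance = 1e-12)
  expect_equal(th$yaw_rate, rep(-omega, th$frames))
  th2 <- make_circular_trajectory(r, -1, omega, "gaze_along_heading")
  expect_equal(th2$yaw, omega * th2$t, tolerance = 1e-12)
})

test_that("omega -> 0 reduces to a static-heading trajectory", {
  tr <- make_circular_trajectory(10, 1, 0, "gaze_along_heading")
  expect_true(all(tr$T == 0))
  expect_true(all(tr$yaw == 0))
})

test_that("target fixation keeps the target stationary in the image", {
  r <- 15; omega <- 2 / r
  for (cond in c("outside_path", "on_path", "inside_path")) {
    tr <- make_circular_trajectory(r, 1, omega, cond)
    q <- tr$descriptor$target
    # target azimuth in camera coordinates, per frame
    az <- vapply(seq_len(tr$frames), function(i) {
      v <- q - tr$P[i, ]
      atan2(v[1], v[3]) - tr$yaw[i]
    }, numeric(1))
    drift <- max(abs(diff(az))) * 180 / pi
    expect_lt(drift, 1e-3)  # degrees per frame
  }
})

test_that("target rotation rate has the analytic limits", {
  # target at (effective) infinity along the heading: azimuth frozen
  rate <- target_rotation_rate(c(0, 1.6, 0), c(0, 0, 2), c(0, 1.6, 1e9))
  expect_equal(rate, 0, tolerance = 1e-12)
  # mirrored targets across a straight path give opposite equal rates
  left <- target_rotation_rate(c(0, 1.6, 0), c(0, 0, 2), c(-3, 1.6, 10))
  right <- target_rotation_rate(c(0, 1.6, 0), c(0, 0, 2), c(3, 1.6, 10))
  expect_equal(left, -right, tolerance = 1e-12)
  expect_gt(abs(left), 0)
  # passing through the target is singular
  expect_error(target_rotation_rate(c(1, 1.6, 5), c(0, 0, 2),
                                    c(1, 1.6, 5)),
               "singular")
})

test_that("pursuit conditions share camera kinematics, not eye signals", {
  r <- 15; omega <- 2 / r
  a <- make_circular_trajectory(r, 1, omega, "orient_along_heading")
  b <- make_circular_trajectory(r, 1, omega, "orient_along_z")
  expect_equal(a$yaw, b$yaw, tolerance = 1e-12)
  expect_equal(a$yaw_rate, b$yaw_rate, tolerance = 1e-12)
  expect_equal(b$eye_rate - a$eye_rate, rep(-omega, a$frames),
               tolerance = 1e-12)
  # with the default pursuit rate the heading-oriented observer needs no
  # eye movement at all
  expect_equal(a$eye_rate, rep(0, a$frames))
})

test_that("straight trajectories translate along Z at constant rotation", {
  tr <- make_straight_rotation_trajectory(2, 0.05)
  expect_equal(tr$T, matrix(rep(c(0, 0, 2), each = tr$frames), ncol = 3),
               ignore_attr = TRUE)
  expect_equal(tr$yaw_rate, rep(0.05, tr$frames))
  expect_equal(tr$P[, 3], 2 * tr$t, tolerance = 1e-12)
})
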