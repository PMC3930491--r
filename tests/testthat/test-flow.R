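cam <- camera_model()

test_that("flow vanishes at the focus of expansion", {
  sc <- make_scene("ground_plane", 1, seed = 1)
  sc$dots[1, ] <- c(0, 1.6, 10)  # straight ahead of the eye
  tr <- make_straight_rotation_trajectory(2, 0)
  fl <- compute_flow(sc, tr, cam, 1)
  expect_equal(fl$n_visible, 1L)
  expect_equal(c(fl$x, fl$y, fl$u, fl$v), c(0, 0, 0, 0), tolerance = 1e-12)
})

test_that("translational flow magnitude scales as 1/Z", {
  tr <- make_straight_rotation_trajectory(2, 0)
  mk <- function(z) {
    sc <- make_scene("ground_plane", 1, seed = 1)
    sc$dots[1, ] <- c(0.3 * z, 1.6 - 0.2 * z, z)  # same image position
    fl <- compute_flow(sc, tr, cam, 1)
    sqrt(fl$u^2 + fl$v^2)
  }
  expect_equal(mk(5) / mk(10), 2, tolerance = 1e-9)
})

test_that("rotation-only flow is independent of depth", {
  tr <- make_straight_rotation_trajectory(0, 0.1)
  mk <- function(z) {
    sc <- make_scene("ground_plane", 1, seed = 1)
    sc$dots[1, ] <- c(0.2 * z, 1.6 + 0.1 * z, z)
    fl <- compute_flow(sc, tr, cam, 1)
    c(fl$u, fl$v)
  }
  expect_equal(mk(3), mk(30), tolerance = 1e-12)
})

test_that("analytic flow matches the finite-difference projection oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:25) {
    sc <- make_scene("ground_plane", 40, seed = i)
    kind <- i %% 3
    tr <- if (kind == 0) {
      make_straight_rotation_trajectory(runif(1, 0.5, 3),
                                        runif(1, -0.2, 0.2))
    } else {
      make_circular_trajectory(runif(1, 8, 30), sample(c(-1, 1), 1),
                               runif(1, 0.02, 0.15),
                               sample(c(gaze_conditions), 1))
    }
    fr <- sample(tr$frames, 1)
    worst <- max(worst, fd_flow_max_rel_error(sc, tr, cam, fr))
  }
  expect_lt(worst, 1e-4)
})

test_that("dots behind the camera or outside the view are clipped", {
  sc <- make_scene("ground_plane", 3, seed = 1)
  sc$dots[1, ] <- c(0, 1.6, -5)    # behind
  sc$dots[2, ] <- c(100, 1.6, 5)   # far outside horizontally
  sc$dots[3, ] <- c(0, 0, 10)      # visible ground dot
  tr <- make_straight_rotation_trajectory(2, 0)
  fl <- compute_flow(sc, tr, cam, 1)
  expect_equal(fl$n_visible, 1L)
  expect_true(all(abs(atan2(fl$x, cam$focal_length)) <=
                    (cam$fov_h / 2) * pi / 180))
  expect_error(compute_flow(sc, tr, cam, 61), "frame")
})

test_that("mirror symmetry: negating world x and lambda mirrors the flow", {
  sc <- make_scene("ground_plane", 60, seed = 11)
  scm <- sc
  scm$dots[, 1] <- -scm$dots[, 1]
  a <- make_circular_trajectory(15, 1, 0.1, "gaze_along_heading")
  b <- make_circular_trajectory(15, -1, 0.1, "gaze_along_heading")
  for (fr in c(1, 30, 60)) {
    fa <- compute_flow(sc, a, cam, fr)
    fb <- compute_flow(scm, b, cam, fr)
    oa <- order(fa$x, fa$y)
    ob <- order(-fb$x, fb$y)
    expect_equal(fa$x[oa], -fb$x[ob], tolerance = 1e-12)
    expect_equal(fa$y[oa], fb$y[ob], tolerance = 1e-12)
    expect_equal(fa$u[oa], -fb$u[ob], tolerance = 1e-12)
    expect_equal(fa$v[oa], fb$v[ob], tolerance = 1e-12)
  }
})
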