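cam <- camera_model()

trial_row <- function(spirality, radius = 15, lambda = 1) {
  data.frame(radius = radius, lambda = lambda,
             spirality_signed = spirality)
}

test_that("path error is the aligned spirality difference", {
  # lambda = +1 trials: aligned spirality equals the signed spirality
  expect_equal(path_error(trial_row(0.4), trial_row(0.3)), 0.1,
               tolerance = 1e-12)
  expect_equal(path_error(trial_row(-0.4, lambda = -1),
                          trial_row(-0.3, lambda = -1)), 0.1,
               tolerance = 1e-12)
  expect_equal(path_error(trial_row(0.2), trial_row(0.2)), 0)
  expect_error(path_error(trial_row(0.2, radius = 10), trial_row(0.2)),
               "radius")
  expect_error(path_error(trial_row(0.2, lambda = -1), trial_row(0.2)),
               "radius|direction")
})

test_that("heading error is signed into path-curvature coordinates", {
  tr <- make_straight_rotation_trajectory(2, 0)
  row <- data.frame(heading_az = 3)
  expect_equal(heading_error(row, tr), -3)  # straight path, true az 0
  expect_error(heading_error(data.frame(heading_az = NA_real_), tr),
               "no heading")
})

test_that("tanh fitting recovers noiseless parameters exactly", {
  xs <- seq(-5, 5, by = 1)
  fit <- fit_tanh(xs, 4.2 * tanh(0.6 * xs))
  expect_equal(fit$a, 4.2, tolerance = 1e-6)
  expect_equal(fit$b, 0.6, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("tanh fitting conventions: flat data and degenerate input", {
  fit <- fit_tanh(-3:3, rep(0, 7))
  expect_equal(fit$a, 0)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_tanh(1:3, 1:3), "at least 4")
})

test_that("tanh fitting recovers parameters from noisy data", {
  set.seed(30)
  xs <- rep(seq(-5, 5, by = 1), 8)
  sigma <- 0.3
  ys <- 3 * tanh(0.5 * xs) + rnorm(length(xs), sd = sigma)
  fit <- fit_tanh(xs, ys)
  # generous 3-sigma-scale windows for an 88-point fit
  expect_lt(abs(fit$a - 3), 3 * sigma)
  expect_lt(abs(fit$b - 0.5), 0.5)
  expect_gt(fit$r_squared, 0.9)
})

test_that("experiment reports are reproducible and self-consistent", {
  bank <- build_template_bank(cam, n_pattern = 11, n_x = 9, n_y = 3)
  run_args <- list(radii = 15, conditions = c("z_axis",
                                              "gaze_along_heading"),
                   reps = 3, seed = 5, n_dots = 60, camera = cam,
                   bank = bank)
  a <- do.call(run_gaze_experiment, run_args)
  b <- do.call(run_gaze_experiment, run_args)
  expect_identical(a$trials, b$trials)

  # aggregates are recomputable from the raw trial table
  tr <- a$trials[a$trials$condition == "z_axis", ]
  s <- a$summary[a$summary$condition == "z_axis", ]
  expect_equal(s$mean_path_error, mean(tr$path_error))
  expect_equal(s$sem_path_error,
               sd(tr$path_error) / sqrt(nrow(tr)))

  # calibration condition has zero path error by construction
  cal <- a$trials[a$trials$condition == "gaze_along_heading", ]
  expect_true(all(cal$path_error == 0))
})

test_that("the gaze experiment requires its calibration condition", {
  expect_error(run_gaze_experiment(radii = 15, conditions = "z_axis",
                                   reps = 2),
               "calibration")
})

test_that("CW and CCW traversals give mirror-antisymmetric readouts", {
  bank <- build_template_bank(cam, n_pattern = 11, n_x = 9, n_y = 3)
  sc <- make_scene("ground_plane", 80, seed = 40)
  scm <- sc; scm$dots[, 1] <- -scm$dots[, 1]
  p <- model_params()
  for (cond in c("gaze_along_heading", "inside_path")) {
    ta <- make_circular_trajectory(15, 1, 2 / 15, cond)
    tb <- make_circular_trajectory(15, -1, 2 / 15, cond)
    aa <- run_trial(sc, ta, cam, p, bank)
    ab <- run_trial(scm, tb, cam, p, bank)
    expect_equal(readout_curvature(aa), -readout_curvature(ab),
                 tolerance = 1e-12)
    expect_equal(readout_heading(aa, cam)[["azimuth"]],
                 -readout_heading(ab, cam)[["azimuth"]],
                 tolerance = 1e-9)
  }
})

test_that("zero pursuit gain collapses the two pursuit conditions", {
  bank <- build_template_bank(cam, n_pattern = 11, n_x = 9, n_y = 3)
  sc <- make_scene("ground_plane", 80, seed = 41)
  p0 <- model_params(gain = 0)
  r <- 15; omega <- 2 / r
  ta <- make_circular_trajectory(r, 1, omega, "orient_along_heading")
  tb <- make_circular_trajectory(r, 1, omega, "orient_along_z")
  za <- run_trial(sc, ta, cam, p0, bank)
  zb <- run_trial(sc, tb, cam, p0, bank)
  expect_equal(za$z, zb$z, tolerance = 1e-12)
  # with the gain field on, the eye-velocity signal differentiates them
  p1 <- model_params(gain = 1)
  za1 <- run_trial(sc, ta, cam, p1, bank)
  zb1 <- run_trial(sc, tb, cam, p1, bank)
  expect_gt(max(abs(za1$z - zb1$z)), 1e-9)
})
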