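cam <- camera_model()

test_that("the quiescent network is a fixed point of the dynamics", {
  bank <- toy_bank()
  z <- numeric(bank$n_units)
  S <- numeric(bank$n_units)
  for (i in 1:50) z <- step_dynamics(z, S, bank, model_params(), 0.01)
  expect_equal(z, numeric(bank$n_units))
})

test_that("without input, activity decays monotonically to zero", {
  bank <- toy_bank()
  p <- model_params()
  z <- rep(0.6, bank$n_units)
  prev <- z
  for (i in 1:400) {
    z <- step_dynamics(z, numeric(bank$n_units), bank, p, 0.01)
    expect_true(all(z <= prev + 1e-12))
    prev <- z
  }
  expect_lt(max(z), 1e-3)
})

test_that("the compiled integrator reproduces the reference R step", {
  set.seed(20)
  bank <- toy_bank(5, 3, 2)
  p <- model_params(dt_substeps = 4)
  S <- matrix(runif(bank$n_units * 6, 0, 0.25), ncol = 6)
  zc <- mstpath:::integrate_scores(S, bank, p, frame_rate = 20)
  z <- numeric(bank$n_units)
  h <- (1 / 20) / 4
  zr <- matrix(0, bank$n_units, 6)
  for (fr in 1:6) {
    for (k in 1:4) z <- step_dynamics(z, S[, fr], bank, p, h)
    zr[, fr] <- z
  }
  expect_equal(zc, zr, tolerance = 1e-10)
})

test_that("activities stay within [0, U] for arbitrary bounded input", {
  set.seed(21)
  bank <- toy_bank(7, 3, 2)
  for (i in 1:5) {
    S <- matrix(runif(bank$n_units * 10, -1, 1), ncol = 10)
    z <- mstpath:::integrate_scores(S, bank, model_params(), 60)
    expect_true(all(z >= 0 & z <= 1))
  }
})

test_that("static input yields soft winner-take-all sharpening", {
  set.seed(22)
  bank <- toy_bank(5, 1, 1)
  p <- model_params()
  s <- c(0.02, 0.04, 0.3, 0.06, 0.05)
  S <- matrix(rep(s, 40), ncol = 40)  # 2 s at 20 Hz = 20 time constants
  z <- mstpath:::integrate_scores(S, bank, p, 20)
  expect_equal(which.max(z[, 40]), which.max(s))
  ratio <- z[which.max(s), ] / apply(z[-which.max(s), , drop = FALSE], 2,
                                     max)
  late <- ratio[10:40]
  expect_true(all(diff(late) >= -1e-6))  # non-decreasing after transient
})

test_that("a 3-unit network converges to the argmax of its input", {
  bank <- toy_bank(3, 1, 1)
  p <- model_params()
  s <- c(0.02, 0.03, 0.3)
  # long fine-step integration
  z <- numeric(3)
  for (i in 1:8000) z <- step_dynamics(z, s, bank, p, 0.005)
  expect_equal(which.max(z), 3L)
  expect_lt(max(z[1:2]), 0.1 * z[3])
})

test_that("lesions zero their pool and restore bitwise", {
  p <- model_params()
  pl <- lesion(p, "spatial")
  expect_true(pl$lesions[["spatial"]])
  expect_identical(lesion(pl, "spatial", FALSE), p)
  expect_error(lesion(p, "nonsense"), "unknown pool")

  # zeroing W is equivalent to lesioning the spatial pool
  set.seed(23)
  bank <- toy_bank(5, 3, 1)
  z <- runif(bank$n_units, 0, 0.5)
  S <- runif(bank$n_units, 0, 0.3)
  a <- step_dynamics(z, S, bank, model_params(W = 0), 0.01)
  b <- step_dynamics(z, S, bank, lesion(model_params(), "spatial"), 0.01)
  expect_equal(a, b, tolerance = 1e-14)

  # lesioned and intact trajectories diverge once inhibition acts
  zi <- z; zl <- z
  for (i in 1:50) {
    zi <- step_dynamics(zi, S, bank, p, 0.01)
    zl <- step_dynamics(zl, S, bank, pl, 0.01)
  }
  expect_gt(max(abs(zi - zl)), 1e-6)
})

test_that("readouts report the argmax unit with deterministic ties", {
  bank <- toy_bank(5, 3, 1)
  u <- bank$units
  i <- which(u$spirality > 0.5 & u$orientation < 0)[1]
  z <- numeric(bank$n_units); z[i] <- 0.4
  # a weaker radial-expansion peak at a different CoM carries the heading
  j <- which(u$orientation == 0 & cos(u$phi) > 0 & u$cx != u$cx[i])[1]
  z[j] <- 0.2
  act <- toy_activity(bank, z)
  expect_equal(readout_curvature(act), -u$spirality[i])
  hd <- readout_heading(act, cam)
  expect_equal(hd[["azimuth"]], atan(u$cx[j]) * 180 / pi)
  expect_equal(hd[["elevation"]], atan(u$cy[j]) * 180 / pi)

  # tie: prefer lower spirality, then the less eccentric CoM
  j <- which(u$spirality < 1e-12)
  z2 <- numeric(bank$n_units); z2[c(i, j[1])] <- 0.4
  expect_equal(readout_curvature(toy_activity(bank, z2)), 0)

  expect_error(readout_curvature(toy_activity(bank,
                                              numeric(bank$n_units))),
               "no estimate")
})

test_that("radial-only activity reads out zero curvature", {
  bank <- toy_bank(5, 3, 1)
  z <- numeric(bank$n_units)
  z[bank$units$orientation == 0] <- 0.3
  expect_equal(readout_curvature(toy_activity(bank, z)), 0)
})
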