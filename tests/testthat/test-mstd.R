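cam <- camera_model()

test_that("transfer is a thresholded saturating sigmoid", {
  expect_equal(transfer(c(-1, 0, 0.01)), c(0, 0, 0))
  expect_equal(transfer(0.01 + 0.07), 0.5)
  expect_equal(transfer(1e6), 1, tolerance = 1e-9)
  set.seed(9)
  x <- sort(runif(200, -0.5, 2))
  expect_true(all(diff(transfer(x)) >= 0))
})

test_that("match score of perfectly aligned flow is the weight sum", {
  set.seed(10)
  tp <- make_template(runif(1, 0, 2 * pi), c(0.1, -0.2))
  x <- runif(40, -1, 1); y <- runif(40, -0.7, 0.7)
  tf <- template_field(tp, x, y)
  fl <- toy_flow(x, y, 0.5 * tf[, "tx"], 0.5 * tf[, "ty"])
  s <- match_score(fl, tp, sigma_d = 10, camera = cam)
  d <- sqrt((x - 0.1)^2 + (y + 0.2)^2)
  expect_equal(s, sum(exp(-d / (10 * pi / 180))) / 40, tolerance = 1e-12)
  expect_gt(s, 0)
})

test_that("radial flow is orthogonal to the center template at the same CoM", {
  set.seed(11)
  com <- c(-0.3, 0.2)
  x <- runif(30, -1, 1); y <- runif(30, -0.7, 0.7)
  fr <- template_field(make_template(0, com), x, y)
  fl <- toy_flow(x, y, fr[, "tx"], fr[, "ty"])
  s <- match_score(fl, make_template(pi / 2, com), sigma_d = 10,
                   camera = cam)
  expect_equal(s, 0, tolerance = 1e-12)
})

test_that("match scores agree with the scalar-loop oracle", {
  set.seed(12)
  for (i in 1:10) {
    fl <- toy_flow(runif(30, -1, 1), runif(30, -0.7, 0.7),
                   rnorm(30), rnorm(30))
    tp <- make_template(runif(1, 0, 2 * pi), runif(2, -0.5, 0.5))
    s <- match_score(fl, tp, sigma_d = 7, camera = cam)
    expect_equal(s, brute_match_oracle(fl, tp, 7, cam), tolerance = 1e-12)
  }
})

test_that("bank scoring equals per-template scoring", {
  set.seed(13)
  bank <- build_template_bank(cam, n_pattern = 7, n_x = 3, n_y = 2)
  fl <- toy_flow(runif(25, -1, 1), runif(25, -0.7, 0.7),
                 rnorm(25), rnorm(25))
  S <- mstpath:::bank_match_scores(fl, bank, sigma_d = 6, camera = cam)
  for (i in sample(bank$n_units, 12)) {
    tp <- make_template(bank$units$phi[i],
                        c(bank$units$cx[i], bank$units$cy[i]))
    expect_equal(S[i], match_score(fl, tp, 6, cam), tolerance = 1e-12)
  }
})

test_that("match scores are bounded by 1 in magnitude", {
  set.seed(14)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    fl <- toy_flow(runif(n, -2, 2), runif(n, -2, 2), rnorm(n), rnorm(n))
    tp <- make_template(runif(1, 0, 2 * pi), runif(2, -2, 2))
    worst <- max(worst, abs(match_score(fl, tp, runif(1, 1, 30), cam)))
  }
  expect_lte(worst, 1)
})

test_that("the generator template achieves the top score at its CoM", {
  set.seed(15)
  bank <- build_template_bank(cam, n_pattern = 23, n_x = 1, n_y = 1)
  for (k in c(0, 5, 11, 17)) {
    phi <- bank$units$phi[k + 1]
    tp <- make_template(phi, c(0, 0))
    x <- runif(60, -1, 1); y <- runif(60, -0.7, 0.7)
    tf <- template_field(tp, x, y)
    fl <- toy_flow(x, y, tf[, "tx"], tf[, "ty"])
    S <- mstpath:::bank_match_scores(fl, bank, 10, cam)
    expect_equal(unname(which.max(S)), k + 1)
  }
})

test_that("empty flow has no defined match score", {
  fl <- toy_flow(numeric(0), numeric(0), numeric(0), numeric(0))
  expect_error(match_score(fl, make_template(0, c(0, 0)), 10, cam),
               "empty")
})

test_that("the gain field cancels pursuit rotation exactly at g = 1", {
  sc <- make_scene("frontoparallel_planes", 80, seed = 16)
  rho <- 0.08
  # straight travel viewed with a pursuing eye vs. a fixating one
  with_rot <- compute_flow(sc, make_straight_rotation_trajectory(2, rho),
                           cam, 1)
  no_rot <- compute_flow(sc, make_straight_rotation_trajectory(2, 0),
                         cam, 1)
  comp <- apply_gain_field(with_rot, eye_rate = rho, gain = 1, camera = cam)
  # same frame-1 geometry, so samples align one-to-one
  expect_equal(comp$u, no_rot$u, tolerance = 1e-6)
  expect_equal(comp$v, no_rot$v, tolerance = 1e-6)
  # zero eye velocity is the identity
  expect_identical(apply_gain_field(no_rot, 0, 1, cam), no_rot)
  # partial gain strictly reduces the residual rotation magnitude
  partial <- apply_gain_field(with_rot, rho, 0.5, cam)
  res_full <- sum((with_rot$u - no_rot$u)^2 + (with_rot$v - no_rot$v)^2)
  res_half <- sum((partial$u - no_rot$u)^2 + (partial$v - no_rot$v)^2)
  expect_lt(res_half, res_full)
})
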