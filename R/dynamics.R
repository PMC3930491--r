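# Per-orientation unit counts within one CoM hypercolumn, and pool sizes
# used when `pool_scale = "mean"`.
bank_pool_info <- function(bank) {
  o <- bank$units$orientation[bank$units$com_index == 1L]
  list(n_pos = sum(o > 0), n_neg = sum(o < 0), n_zero = sum(o == 0))
}

#' One explicit integration step of the MSTd competitive field
#'
#' Advances the shunting recurrent competitive field by one explicit Euler
#' step of length `dt`. Each unit `c` obeys
#' \deqn{\dot z_c = A\,[\,-D z_c + (U - z_c)(f(z_c) + f(S_c))
#'   - z_c\,(I^{spiral}_c + I^{orient}_c + W\,I^{spatial}_c)\,]}
#' with `f` the [transfer()] function and three inhibition pools:
#' *spiral_space* (same CoM and orientation wing, different spirality;
#' purely radial units, which have no orientation, compete with the whole
#' hypercolumn), *orientation* (same CoM, opposite orientation wing), and
#' *spatial* (all units at other CoMs, weighted by `W`). With
#' `pool_scale = "mean"` each pool's transferred activity is averaged over
#' the pool size; with `"sum"` raw sums are used. Lesioned pools contribute
#' zero. The state is clamped to `[0, U]` after the step.
#'
#' @param z Activation vector (length `bank$n_units`), within `[0, U]`.
#' @param S Match-score input vector (same length).
#' @param bank The [build_template_bank()] bank.
#' @param params [model_params()].
#' @param dt Step length in seconds.
#' @return The new activation vector.
#' @export
step_dynamics <- function(z, S, bank, params = model_params(), dt) {
  if (any(!is.finite(z)) || any(!is.finite(S))) {
    stop("non-finite state in dynamics integration", call. = FALSE)
  }
  u <- bank$units
  f <- transfer(z, params$gamma_r, params$beta)
  fS <- transfer(S, params$gamma, params$beta)
  info <- bank_pool_info(bank)
  n_pat <- bank$n_pattern
  gsum <- function(v, idx) {
    out <- numeric(bank$n_com)
    t <- tapply(v, idx, sum)
    out[as.integer(names(t))] <- t
    out
  }
  pos <- u$orientation > 0
  neg <- u$orientation < 0
  zero <- u$orientation == 0
  sum_pos <- gsum(f[pos], u$com_index[pos])
  sum_neg <- gsum(f[neg], u$com_index[neg])
  sum_zero <- gsum(f[zero], u$com_index[zero])
  G <- sum_pos + sum_neg + sum_zero
  Ftot <- sum(G)
  j <- u$com_index
  wing <- ifelse(pos, sum_pos[j] + sum_zero[j],
                 ifelse(neg, sum_neg[j] + sum_zero[j], G[j]))
  spiral <- wing - f
  orient <- ifelse(pos, sum_neg[j], ifelse(neg, sum_pos[j], 0))
  spatial <- Ftot - G[j]
  n_spiral <- ifelse(pos, info$n_pos + info$n_zero,
                     ifelse(neg, info$n_neg + info$n_zero, n_pat)) - 1
  n_orient <- ifelse(pos, info$n_neg, ifelse(neg, info$n_pos, 0))
  n_spatial <- (bank$n_com - 1) * n_pat
  if (params$pool_scale == "mean") {
    spiral <- ifelse(n_spiral > 0, spiral / pmax(n_spiral, 1), 0)
    orient <- ifelse(n_orient > 0, orient / pmax(n_orient, 1), 0)
    spatial <- if (n_spatial > 0) spatial / n_spatial else 0
  }
  les <- params$lesions
  inhib <- (!les[["spiral_space"]]) * spiral +
    (!les[["orientation"]]) * orient +
    (!les[["spatial"]]) * params$W * spatial
  dz <- params$A * (-params$D * z + (params$U - z) * (f + fS) - z * inhib)
  pmin(pmax(z + dt * dz, 0), params$U)
}

# Per-frame match-score matrix for a trial (units x frames). Kept separate
# from the integration so lesion studies can reuse the scores.
trial_scores <- function(scene, trajectory, camera = camera_model(),
                         params = model_params(), bank) {
  S <- matrix(0, nrow = bank$n_units, ncol = trajectory$frames)
  mt <- mt_params()
  for (fr in seq_len(trajectory$frames)) {
    fl <- compute_flow(scene, trajectory, camera, fr)
    if (fl$n_visible == 0L) {
      warning(sprintf("frame %d: all dots clipped; zero input", fr),
              call. = FALSE)
      next
    }
    pooled <- pool_flow(fl, mt, camera)
    er <- trajectory$eye_rate[fr]
    if (er != 0 && params$gain != 0) {
      pooled <- apply_gain_field(pooled, er, params$gain, camera)
    }
    S[, fr] <- bank_match_scores(pooled, bank, params$sigma_d, camera)
  }
  S
}

# Integrate the competitive field across a trial's match scores. Activity
# is carried across frames (temporal accumulation is the mechanism), with
# `dt_substeps` Euler substeps per frame interval and local step halving
# when a step would overshoot.
integrate_scores <- function(S, bank, params = model_params(), frame_rate) {
  info <- bank_pool_info(bank)
  zh <- cpp_mstd_integrate(
    S, bank$units$com_index, bank$units$orientation,
    bank$n_com, bank$n_pattern,
    info$n_pos, info$n_neg, info$n_zero,
    params$A, params$D, params$U, params$W, params$gamma, params$gamma_r,
    params$beta,
    as.logical(params$lesions[["spiral_space"]]),
    as.logical(params$lesions[["orientation"]]),
    as.logical(params$lesions[["spatial"]]),
    identical(params$pool_scale, "mean"),
    1 / frame_rate, params$dt_substeps
  )
  if (any(!is.finite(zh))) {
    stop("non-finite state in dynamics integration", call. = FALSE)
  }
  zh
}

#' Run one full model trial
#'
#' Per frame: first-order flow (model V1), Gaussian pooling (model MT),
#' extra-retinal gain-field modulation when the trajectory includes
#' pursuit eye movements, template matching against the bank, and
#' integration of the recurrent competitive field across the frame
#' interval. Activity is *not* reset between frames; its temporal
#' accumulation is part of the mechanism.
#'
#' @param scene [make_scene()] scene.
#' @param trajectory [make_circular_trajectory()] or
#'   [make_straight_rotation_trajectory()] trajectory.
#' @param camera [camera_model()].
#' @param params [model_params()].
#' @param bank Optional prebuilt [build_template_bank()]; defaults to the
#'   full 11500-unit bank for `camera`.
#' @return An object of class `mst_activity`: list with `z` (units x
#'   frames activation history), `S` (match scores), `bank`, `params`,
#'   `peak_unit` (per-frame argmax), `frame_rate`, and the trajectory
#'   descriptor.
#' @export
run_trial <- function(scene, trajectory, camera = camera_model(),
                      params = model_params(), bank = NULL) {
  if (is.null(bank)) bank <- build_template_bank(camera)
  S <- trial_scores(scene, trajectory, camera, params, bank)
  z <- integrate_scores(S, bank, params, trajectory$frame_rate)
  structure(
    list(z = z, S = S, bank = bank, params = params,
         peak_unit = apply(z, 2, which.max),
         frame_rate = trajectory$frame_rate,
         trajectory = trajectory$descriptor,
         gaze_condition = trajectory$gaze_condition),
    class = "mst_activity"
  )
}

#' @export
print.mst_activity <- function(x, ...) {
  cat(sprintf("<mst_activity> %d units x %d frames (%s)\n",
              nrow(x$z), ncol(x$z), x$gaze_condition))
  invisible(x)
}

# Deterministic argmax of final-frame activity: ties broken toward lower
# spirality, then smaller CoM eccentricity.
peak_unit_index <- function(activity) {
  z <- activity$z[, ncol(activity$z)]
  if (all(z <= 0)) {
    stop("no estimate: all MSTd activities are zero", call. = FALSE)
  }
  u <- activity$bank$units
  cand <- which(z >= max(z) - 1e-15)
  cand[order(u$spirality[cand], u$cx[cand]^2 + u$cy[cand]^2)][1]
}

#' Path-curvature readout: signed peak spirality
#'
#' Returns the spirality of the globally most active unit at the end of
#' the trial, signed by the unit's orientation (+ for CCW templates, - for
#' CW templates). Purely radial winners give 0. Ties are broken
#' deterministically toward lower spirality, then smaller CoM
#' eccentricity.
#'
#' @param activity An `mst_activity` from [run_trial()].
#' @return Signed spirality in `[-1, 1]`.
#' @export
readout_curvature <- function(activity) {
  i <- peak_unit_index(activity)
  u <- activity$bank$units
  u$spirality[i] * u$orientation[i]
}

#' Heading readout: visuotopic position of the expansion-subpopulation peak
#'
#' Heading is encoded by the visuotopic position (center of motion) of
#' the most active unit among those tuned to radial expansion: a spiral
#' or center unit's CoM marks the flow's rotation center rather than the
#' direction of travel, so the heading readout interrogates the
#' expansion subpopulation of the same activity state. The CoM offset of
#' that unit is converted to visual angle.
#'
#' @param activity An `mst_activity`.
#' @param camera The [camera_model()] (for the focal length).
#' @return `c(azimuth, elevation)` in degrees.
#' @export
readout_heading <- function(activity, camera = camera_model()) {
  u <- activity$bank$units
  radial <- which(u$orientation == 0L & cos(u$phi) > 0)
  if (length(radial) == 0L) {
    stop("bank contains no radial-expansion units", call. = FALSE)
  }
  z <- activity$z[radial, ncol(activity$z)]
  if (all(z <= 0)) {
    stop("no estimate: all MSTd activities are zero", call. = FALSE)
  }
  cand <- radial[z >= max(z) - 1e-15]
  u2 <- u[cand, , drop = FALSE]
  i <- cand[order(u2$cx^2 + u2$cy^2)][1]
  c(azimuth = iu2deg(u$cx[i], camera), elevation = iu2deg(u$cy[i], camera))
}
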