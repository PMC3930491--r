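#' @section Coordinate and sign conventions:
#' World frame: X rightward, Y up, Z along the observer's initial heading.
#' Camera yaw `psi` is measured so that positive yaw rotates gaze toward
#' +X; the camera forward direction is `(sin psi, 0, cos psi)`. A
#' counter-clockwise path as seen from above (`lambda = +1`) turns the
#' heading toward -X, i.e. has yaw rate `-lambda * omega`. The
#' finite-difference projection oracle in the test-suite, not the
#' convention itself, is the correctness contract for the flow field.
#' @name mstpath-conventions
NULL

#' Names of the simulated-gaze conditions
#'
#' The five circular-path gaze conditions, in the order conventionally
#' reported: `z_axis`, `outside_path`, `on_path`, `inside_path`,
#' `gaze_along_heading`.
#' @export
gaze_conditions <- c("z_axis", "outside_path", "on_path", "inside_path",
                     "gaze_along_heading")

#' Names of the smooth-pursuit conditions
#' @rdname gaze_conditions
#' @export
pursuit_conditions <- c("orient_along_heading", "orient_along_z")

#' Fixation targets for the circular-path gaze conditions
#'
#' The on-path target sits on the future path, `target_arc` meters of world
#' (arc) distance from the start, at eye height. The outside and inside
#' targets are displaced laterally by `offset_deg` degrees of visual angle
#' (as seen from the starting position) away from and toward the center of
#' the circular path, at the same distance from the observer.
#'
#' @param r Path radius (m). @param lambda +1 for CCW, -1 for CW traversal.
#' @param eye_height Eye height (m). @param target_arc Arc distance (m) of
#'   the on-path target; `NULL` (default) places it 0.3 radians of arc
#'   ahead (`target_arc = 0.3 * r`), so the target starts about 8.6
#'   degrees off the initial heading for every radius, the fixation
#'   geometry is self-similar across the radius sweep, and a one-second
#'   trial never overruns the target. @param offset_deg Lateral
#'   visual-angle offset of the outside/inside targets (deg).
#' @return Named list of 3-vectors `on_path`, `outside_path`, `inside_path`.
#' @export
gaze_targets <- function(r, lambda = 1, eye_height = 1.6, target_arc = NULL,
                         offset_deg = 10) {
  if (is.null(target_arc)) target_arc <- 0.3 * r
  theta <- target_arc / r
  on_path <- c(-lambda * r * (1 - cos(theta)), eye_height, r * sin(theta))
  az_on <- atan2(on_path[1], on_path[3])
  rho <- sqrt(on_path[1]^2 + on_path[3]^2)
  off <- deg2rad(offset_deg)
  # inside = toward the circle center (-lambda * X side)
  az_out <- az_on + lambda * off
  az_in <- az_on - lambda * off
  list(
    on_path = on_path,
    outside_path = c(rho * sin(az_out), eye_height, rho * cos(az_out)),
    inside_path = c(rho * sin(az_in), eye_height, rho * cos(az_in))
  )
}

#' Yaw rate that keeps a world target fixated
#'
#' Returns the rate of change of the observer-to-target azimuth; a camera
#' rotating at this yaw rate keeps the target's image projection
#' stationary. Rows of `P` and `T` are per-frame observer positions and
#' translation velocities.
#'
#' @param P n x 3 matrix (or 3-vector) of observer positions (m).
#' @param T n x 3 matrix (or 3-vector) of translation velocities (m/s).
#' @param target World position of the fixated target (3-vector).
#' @return Yaw rate(s) in rad/s, one per row of `P`.
#' @export
target_rotation_rate <- function(P, T, target) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (is.null(dim(T))) T <- matrix(T, nrow = 1)
  a <- target[1] - P[, 1]
  b <- target[3] - P[, 3]
  d2 <- a^2 + b^2
  if (any(d2 < 1e-12)) {
    stop("singular geometry: observer passes through the fixation target",
         call. = FALSE)
  }
  (-T[, 1] * b + a * T[, 3]) / d2
}

#' Observer trajectory along a circular path
#'
#' The observer moves at constant speed `r * omega` along a circle of
#' radius `r`, starting at the world origin heading along +Z, traversing
#' counter-clockwise (seen from above) for `lambda = +1` or clockwise for
#' `lambda = -1`. Motion is parallel to the ground (no vertical
#' translation) and trials never exceed a quarter circle.
#'
#' The camera (gaze) orientation depends on the condition:
#' \describe{
#'   \item{`z_axis`}{Gaze fixed parallel to the world Z axis; the
#'     instantaneous flow is rotation-free radial expansion whose focus
#'     drifts over time.}
#'   \item{`outside_path`, `on_path`, `inside_path`}{Gaze fixates a world
#'     target (see [gaze_targets()]); yaw follows the observer-to-target
#'     azimuth.}
#'   \item{`gaze_along_heading`}{Gaze locked to the heading (tangent)
#'     direction; yaw rate `-lambda * omega`.}
#'   \item{`orient_along_heading`}{Body orientation along heading plus a
#'     smooth-pursuit eye rotation toward the path exterior at rate
#'     `pursuit_rate - omega`; the retinal (camera) kinematics equal those
#'     of `orient_along_z` by construction.}
#'   \item{`orient_along_z`}{Body orientation fixed along Z plus a pursuit
#'     eye rotation toward the path interior at rate `pursuit_rate`.}
#' }
#' The pursuit component is recorded per frame in `eye_rate` and is the
#' signal the MSTd gain field compensates; simulated-gaze conditions have
#' `eye_rate = 0` throughout.
#'
#' @param r Path radius in meters (> 0).
#' @param lambda Traversal direction: +1 CCW (from above), -1 CW.
#' @param omega Angular rate around the circle (rad/s, >= 0).
#' @param gaze_condition One of the conditions listed above.
#' @param target Optional explicit fixation target (world 3-vector);
#'   defaults to the [gaze_targets()] geometry for target conditions.
#' @param frames Number of flow frames in the trial.
#' @param frame_rate Frame rate in Hz.
#' @param eye_height Eye height (m).
#' @param target_arc,target_offset_deg Passed to [gaze_targets()].
#' @param pursuit_rate Pursuit eye speed (rad/s) for the two
#'   `orient_along_*` conditions; defaults to `omega`, the value for which
#'   the tracked target moves with the display's focus of expansion.
#' @return An object of class `mst_trajectory` with per-frame fields `t`,
#'   `P`, `T` (world), `yaw`, `yaw_rate`, `eye_rate`.
#' @export
make_circular_trajectory <- function(r, lambda = 1, omega,
                                     gaze_condition = "gaze_along_heading",
                                     target = NULL, frames = 60,
                                     frame_rate = 60, eye_height = 1.6,
                                     target_arc = NULL,
                                     target_offset_deg = 10,
                                     pursuit_rate = NULL) {
  gaze_condition <- match.arg(gaze_condition,
                              c(gaze_conditions, pursuit_conditions))
  if (!is.numeric(r) || r <= 0) stop("`r` must be positive", call. = FALSE)
  if (!lambda %in% c(-1, 1)) stop("`lambda` must be +1 or -1", call. = FALSE)
  if (omega < 0) stop("`omega` must be non-negative", call. = FALSE)
  duration <- frames / frame_rate
  if (omega * duration > pi / 2 + 1e-9) {
    stop("trial would traverse more than a quarter circle; reduce `omega`, ",
         "`frames`, or increase `frame_rate`", call. = FALSE)
  }
  if (is.null(pursuit_rate)) pursuit_rate <- omega
  if (gaze_condition %in% c("outside_path", "on_path", "inside_path") &&
      is.null(target)) {
    target <- gaze_targets(r, lambda, eye_height, target_arc,
                           target_offset_deg)[[gaze_condition]]
  }
  desc <- list(type = "circular", r = r, lambda = lambda, omega = omega,
               gaze_condition = gaze_condition, target = target,
               eye_height = eye_height, pursuit_rate = pursuit_rate)
  build_trajectory(desc, frames, frame_rate)
}

#' Straight path with added (simulated) rotation
#'
#' The observer translates at constant world velocity along +Z while the
#' camera rotates about the vertical axis at `rotation_rate`, emulating
#' displays in which rotation is simulated while subjects fixate.
#'
#' @param speed Translation speed (m/s).
#' @param rotation_rate Yaw rate (rad/s); positive rotates gaze toward +X.
#' @param frames,frame_rate,eye_height As in [make_circular_trajectory()].
#' @return An `mst_trajectory`.
#' @export
make_straight_rotation_trajectory <- function(speed, rotation_rate,
                                              frames = 60, frame_rate = 60,
                                              eye_height = 1.6) {
  desc <- list(type = "straight", speed = speed,
               rotation_rate = rotation_rate, eye_height = eye_height)
  build_trajectory(desc, frames, frame_rate)
}

# Continuous-time kinematic state of a trajectory descriptor. Exported so
# that simulation code and independent projection-based checks can sample
# the same trajectory at arbitrary times.

#' Kinematic state at an arbitrary time
#'
#' Evaluates a trajectory's analytic descriptor at continuous time `time`
#' (seconds), returning the observer position, world translation velocity,
#' camera yaw, total yaw rate, and the pursuit (eye) component of the yaw
#' rate.
#'
#' @param traj An `mst_trajectory`.
#' @param time Time in seconds (scalar).
#' @return `list(P, T, yaw, yaw_rate, eye_rate)`.
#' @export
trajectory_state <- function(traj, time) {
  d <- traj$descriptor
  h <- d$eye_height
  if (d$type == "straight") {
    return(list(P = c(0, h, d$speed * time), T = c(0, 0, d$speed),
                yaw = d$rotation_rate * time, yaw_rate = d$rotation_rate,
                eye_rate = 0))
  }
  r <- d$r; lambda <- d$lambda; omega <- d$omega
  psi <- -lambda * omega * time
  P <- c(-lambda * r * (1 - cos(omega * time)), h, r * sin(omega * time))
  T <- r * omega * c(sin(psi), 0, cos(psi))
  switch(d$gaze_condition,
    z_axis = list(P = P, T = T, yaw = 0, yaw_rate = 0, eye_rate = 0),
    gaze_along_heading = list(P = P, T = T, yaw = psi,
                              yaw_rate = -lambda * omega, eye_rate = 0),
    orient_along_heading = {
      p <- d$pursuit_rate
      list(P = P, T = T, yaw = -lambda * p * time,
           yaw_rate = -lambda * p, eye_rate = -lambda * (p - omega))
    },
    orient_along_z = {
      p <- d$pursuit_rate
      list(P = P, T = T, yaw = -lambda * p * time,
           yaw_rate = -lambda * p, eye_rate = -lambda * p)
    },
    { # target-fixation conditions
      q <- d$target
      yaw <- atan2(q[1] - P[1], q[3] - P[3])
      rate <- target_rotation_rate(P, T, q)
      list(P = P, T = T, yaw = yaw, yaw_rate = rate, eye_rate = 0)
    }
  )
}

build_trajectory <- function(desc, frames, frame_rate) {
  frames <- as.integer(frames)
  if (frames < 1) stop("`frames` must be at least 1", call. = FALSE)
  t <- (seq_len(frames) - 1) / frame_rate
  states <- lapply(t, function(ti) {
    s <- trajectory_state(structure(list(descriptor = desc),
                                    class = "mst_trajectory"), ti)
    s
  })
  structure(
    list(
      frames = frames, frame_rate = frame_rate, t = t,
      P = do.call(rbind, lapply(states, `[[`, "P")),
      T = do.call(rbind, lapply(states, `[[`, "T")),
      yaw = vapply(states, `[[`, numeric(1), "yaw"),
      yaw_rate = vapply(states, `[[`, numeric(1), "yaw_rate"),
      eye_rate = vapply(states, `[[`, numeric(1), "eye_rate"),
      gaze_condition = if (desc$type == "straight") "straight"
                       else desc$gaze_condition,
      descriptor = desc
    ),
    class = "mst_trajectory"
  )
}

#' @export
print.mst_trajectory <- function(x, ...) {
  d <- x$descriptor
  if (d$type == "straight") {
    cat(sprintf("<mst_trajectory> straight, %g m/s, rotation %.3g rad/s, %d frames @ %g Hz\n",
                d$speed, d$rotation_rate, x$frames, x$frame_rate))
  } else {
    cat(sprintf("<mst_trajectory> circular r = %g m, lambda = %+d, omega = %.3g rad/s, %s, %d frames @ %g Hz\n",
                d$r, d$lambda, d$omega, d$gaze_condition, x$frames,
                x$frame_rate))
  }
  invisible(x)
}
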