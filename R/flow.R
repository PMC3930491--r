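#' First-order optic flow for one frame
#'
#' Projects the scene dots through the pin-hole camera at the trajectory
#' state of frame `frame` and evaluates the first-order
#' (Longuet-Higgins/Prazdny) optic flow at each visible dot:
#' \deqn{u = (x T_z - f T_x)/Z + (xy/f)\,\omega_x - (f + x^2/f)\,\omega_y
#'       + y\,\omega_z}
#' \deqn{v = (y T_z - f T_y)/Z + (f + y^2/f)\,\omega_x - (xy/f)\,\omega_y
#'       - x\,\omega_z}
#' with `T` and `omega` the camera-frame translation and rotation
#' velocities and `Z` the camera-frame depth of the dot. Dots behind the
#' camera (`Z <= 0`) or outside the field of view are excluded, not an
#' error.
#'
#' @param scene An [make_scene()] scene.
#' @param trajectory An `mst_trajectory`.
#' @param camera An [camera_model()].
#' @param frame Frame index (1-based, within the trajectory).
#' @return An object of class `mst_flow`: list with `frame`, `x`, `y`
#'   (image positions of visible dots), `u`, `v` (image velocities),
#'   `n_visible`, and `focal_length`.
#' @export
compute_flow <- function(scene, trajectory, camera = camera_model(), frame) {
  if (frame < 1 || frame > trajectory$frames) {
    stop("`frame` outside the trajectory", call. = FALSE)
  }
  st <- trajectory_state(trajectory, trajectory$t[frame])
  flow_from_state(scene, st, camera, frame)
}

# Flow at an explicit kinematic state (shared by compute_flow and the
# gain-field rotational flow).
flow_from_state <- function(scene, st, camera, frame = NA_integer_) {
  f <- camera$focal_length
  psi <- st$yaw
  right <- c(cos(psi), 0, -sin(psi))
  up <- c(0, 1, 0)
  fwd <- c(sin(psi), 0, cos(psi))
  V <- sweep(scene$dots, 2, st$P)
  Xc <- V %*% right
  Yc <- V %*% up
  Zc <- V %*% fwd
  vis <- Zc > 1e-9 &
    abs(atan2(Xc, Zc)) <= deg2rad(camera$fov_h) / 2 &
    abs(atan2(Yc, Zc)) <= deg2rad(camera$fov_v) / 2
  Xc <- Xc[vis]; Yc <- Yc[vis]; Zc <- Zc[vis]
  x <- f * Xc / Zc
  y <- f * Yc / Zc
  Tc <- c(sum(st$T * right), sum(st$T * up), sum(st$T * fwd))
  om <- c(0, st$yaw_rate, 0)
  uv <- lhp_flow(x, y, Zc, Tc, om, f)
  structure(
    list(frame = frame, x = x, y = y, u = uv$u, v = uv$v,
         n_visible = sum(vis), focal_length = f),
    class = "mst_flow"
  )
}

# The first-order flow equations, shared between translation+rotation flow
# and the rotation-only gain-field flow.
lhp_flow <- function(x, y, Z, Tc, om, f) {
  u <- (x * Tc[3] - f * Tc[1]) / Z +
    (x * y / f) * om[1] - (f + x^2 / f) * om[2] + y * om[3]
  v <- (y * Tc[3] - f * Tc[2]) / Z +
    (f + y^2 / f) * om[1] - (x * y / f) * om[2] - x * om[3]
  list(u = u, v = v)
}

#' @export
print.mst_flow <- function(x, ...) {
  cat(sprintf("<mst_flow> frame %s, %d visible dots\n",
              ifelse(is.na(x$frame), "?", x$frame), x$n_visible))
  invisible(x)
}

#' @export
as.data.frame.mst_flow <- function(x, ...) {
  data.frame(frame = rep(x$frame, x$n_visible), x_img = x$x, y_img = x$y,
             u = x$u, v = x$v)
}
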