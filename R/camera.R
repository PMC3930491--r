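#' Pin-hole camera model
#'
#' Defines the planar pin-hole projection used throughout the simulator.
#' Image coordinates follow the convention x rightward, y upward, z forward
#' (the optical axis), with projection `x_img = f * X / Z`,
#' `y_img = f * Y / Z`. Only points with `Z > 0` whose projection falls
#' inside the field of view are visible.
#'
#' @param focal_length Focal length in image-plane units. Default 1, so the
#'   image coordinates are tangents of visual angle.
#' @param fov_h,fov_v Horizontal and vertical field of view in degrees; must
#'   lie strictly between 0 and 180.
#' @param frame_rate Sampling rate of the flow field in Hz (default 60,
#'   one flow frame per refresh of a 60 Hz display).
#' @return An object of class `mst_camera`.
#' @examples
#' cam <- camera_model()
#' cam$fov_h
#' @export
camera_model <- function(focal_length = 1, fov_h = 110, fov_v = 94,
                         frame_rate = 60) {
  if (!is.numeric(focal_length) || length(focal_length) != 1L ||
      focal_length <= 0) {
    stop("`focal_length` must be a positive scalar", call. = FALSE)
  }
  if (!(fov_h > 0 && fov_h < 180) || !(fov_v > 0 && fov_v < 180)) {
    stop("`fov_h` and `fov_v` must lie in (0, 180) degrees", call. = FALSE)
  }
  if (frame_rate <= 0) stop("`frame_rate` must be positive", call. = FALSE)
  structure(
    list(focal_length = focal_length, fov_h = fov_h, fov_v = fov_v,
         frame_rate = frame_rate),
    class = "mst_camera"
  )
}

#' @export
print.mst_camera <- function(x, ...) {
  cat(sprintf("<mst_camera> f = %g, FOV %g x %g deg, %g Hz\n",
              x$focal_length, x$fov_h, x$fov_v, x$frame_rate))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Angular widths (kernel sigmas, decay constants) are mapped to image-plane
# units with the small-angle factor f * pi / 180, exact at the optical axis.
deg2iu <- function(deg, camera) camera$focal_length * deg2rad(deg)

# Image position -> visual angle in degrees (exact, not small-angle).
iu2deg <- function(iu, camera) rad2deg(atan2(iu, camera$focal_length))

# Evaluate code with a private, restored RNG state so that generators are
# deterministic given `seed` without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one experiment seed into per-trial seeds.
# Trial i under base seed s gets seed (s * 10007 + i) mod 2^31 - 1, kept
# strictly positive so it is always a valid `set.seed()` argument.
fanout_seed <- function(base_seed, index) {
  s <- (as.double(base_seed) * 10007 + as.double(index)) %% 2147483647
  as.integer(s) + 1L
}
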