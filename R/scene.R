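#' Generate a random-dot scene
#'
#' Builds the dot environments used in the simulated psychophysics displays.
#' World coordinates: X rightward, Y upward (ground at Y = 0), Z in the
#' observer's initial heading direction; the observer's eye starts at
#' `(0, eye_height, 0)`.
#'
#' Three scene kinds are supported:
#' \describe{
#'   \item{`ground_plane`}{`n_dots` dots on the ground (`Y = 0`), sampled
#'     uniformly in depth over `depth_range` and, at each depth, uniformly
#'     across the horizontal field of view. Sampling within the viewing
#'     frustum keeps the projected dot density roughly constant across
#'     depths, mirroring displays that equate visible density.}
#'   \item{`frontoparallel_planes`}{Dots split evenly across fronto-parallel
#'     planes at depths `plane_depths`, each plane filling the field of view
#'     at its depth, centered at eye level.}
#'   \item{`room_walls`}{Dots split across the three walls (left, right,
#'     front) of a rectangular room centered on the observer, from floor to
#'     ceiling.}
#' }
#'
#' @param kind Scene kind; one of `"ground_plane"`,
#'   `"frontoparallel_planes"`, `"room_walls"`.
#' @param n_dots Total number of dots (>= 1).
#' @param depth_range Numeric `(near, far)` depth bounds in meters for the
#'   ground plane; `0 < near < far`.
#' @param eye_height Observer eye height above the ground in meters.
#' @param seed Integer seed; the same seed reproduces the dot list exactly.
#' @param camera An [camera_model()] used to size the sampling frustum.
#' @param plane_depths Depths (m) of the fronto-parallel planes.
#' @param room `list(half_width, depth, height)` in meters for
#'   `"room_walls"` scenes.
#' @return An object of class `mst_scene` with fields `kind`, `dots`
#'   (an `n_dots` x 3 matrix of world X, Y, Z), `n_dots`, `depth_range`,
#'   `eye_height`, `seed`.
#' @examples
#' sc <- make_scene("ground_plane", n_dots = 200, seed = 1)
#' nrow(sc$dots)
#' @export
make_scene <- function(kind = c("ground_plane", "frontoparallel_planes",
                                "room_walls"),
                       n_dots = 200, depth_range = c(1.4, 25),
                       eye_height = 1.6, seed = 1L,
                       camera = camera_model(),
                       plane_depths = c(10, 20),
                       room = list(half_width = 4, depth = 4, height = 3)) {
  kind <- match.arg(kind)
  if (!is.numeric(n_dots) || n_dots < 1) {
    stop("`n_dots` must be at least 1", call. = FALSE)
  }
  n_dots <- as.integer(n_dots)
  if (length(depth_range) != 2L || depth_range[1] <= 0 ||
      depth_range[2] < depth_range[1]) {
    stop("`depth_range` must satisfy 0 < near <= far", call. = FALSE)
  }
  half_h <- deg2rad(camera$fov_h) / 2
  half_v <- deg2rad(camera$fov_v) / 2

  dots <- with_seed(seed, {
    switch(kind,
      ground_plane = {
        z <- stats::runif(n_dots, depth_range[1], depth_range[2])
        xmax <- z * tan(half_h)
        x <- stats::runif(n_dots, -xmax, xmax)
        cbind(x, rep(0, n_dots), z)
      },
      frontoparallel_planes = {
        np <- length(plane_depths)
        counts <- rep(n_dots %/% np, np)
        if (n_dots %% np > 0) {
          counts[seq_len(n_dots %% np)] <- counts[seq_len(n_dots %% np)] + 1L
        }
        do.call(rbind, lapply(seq_len(np), function(i) {
          zp <- plane_depths[i]
          x <- stats::runif(counts[i], -zp * tan(half_h), zp * tan(half_h))
          y <- eye_height + stats::runif(counts[i], -zp * tan(half_v),
                                         zp * tan(half_v))
          cbind(x, y, rep(zp, counts[i]))
        }))
      },
      room_walls = {
        counts <- rep(n_dots %/% 3L, 3L)
        if (n_dots %% 3L > 0) {
          counts[seq_len(n_dots %% 3L)] <- counts[seq_len(n_dots %% 3L)] + 1L
        }
        hw <- room$half_width
        left <- cbind(rep(-hw, counts[1]),
                      stats::runif(counts[1], 0, room$height),
                      stats::runif(counts[1], -room$depth, room$depth))
        right <- cbind(rep(hw, counts[2]),
                       stats::runif(counts[2], 0, room$height),
                       stats::runif(counts[2], -room$depth, room$depth))
        front <- cbind(stats::runif(counts[3], -hw, hw),
                       stats::runif(counts[3], 0, room$height),
                       rep(room$depth, counts[3]))
        rbind(left, right, front)
      }
    )
  })
  dimnames(dots) <- list(NULL, c("x", "y", "z"))
  structure(
    list(kind = kind, dots = dots, n_dots = n_dots,
         depth_range = depth_range, eye_height = eye_height,
         seed = as.integer(seed)),
    class = "mst_scene"
  )
}

#' @export
print.mst_scene <- function(x, ...) {
  cat(sprintf("<mst_scene> %s, %d dots, depth %g-%g m, eye height %g m\n",
              x$kind, x$n_dots, x$depth_range[1], x$depth_range[2],
              x$eye_height))
  invisible(x)
}
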