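#' Spiral motion-pattern template
#'
#' A template is a unit direction field on the image plane obtained by
#' interpolating a radial field and a center (circular) field about a
#' shared center of motion (CoM). With `d = p - com`, `rho = |d|`:
#' radial direction `d / rho`, CCW center direction `(-d_y, d_x) / rho`,
#' and the template field
#' \deqn{T(p) = \cos\varphi \; \hat r(p) + \sin\varphi \; \hat c(p),}
#' which is automatically unit length because the two basis fields are
#' pointwise orthonormal. The pattern angle `phi` parameterizes the spiral
#' continuum: 0 expansion, pi/2 CCW center, pi contraction, 3*pi/2 CW
#' center; intermediate angles are spirals. Spirality is `|sin(phi)|`
#' (0 = radial, 1 = center) and the orientation is the sign of
#' `sin(phi)` (+1 CCW, -1 CW, 0 purely radial). The field is undefined
#' exactly at the CoM; that point is excluded from matching.
#'
#' @param phi Pattern angle in `[0, 2*pi)`.
#' @param com Image-plane CoM offset, `c(C_x, C_y)`.
#' @return An object of class `mst_template` with fields `phi`, `com`,
#'   `spirality`, `orientation` (+1/-1/0), `sense`
#'   (`"expand"`/`"contract"`/`"center"`).
#' @examples
#' tp <- make_template(pi / 4, c(0, 0))
#' template_field(tp, 1, 0)  # 45-degree spiral direction
#' @export
make_template <- function(phi, com = c(0, 0)) {
  phi <- phi %% (2 * pi)
  s <- sin(phi); c_ <- cos(phi)
  orientation <- if (abs(s) < 1e-12) 0L else as.integer(sign(s))
  sense <- if (abs(c_) < 1e-12) "center" else
    if (c_ > 0) "expand" else "contract"
  structure(
    list(phi = phi, com = com, spirality = abs(s),
         orientation = orientation, sense = sense),
    class = "mst_template"
  )
}

#' Evaluate a template's unit direction field
#'
#' @param template An [make_template()] object.
#' @param x,y Image-plane coordinates.
#' @return A matrix with columns `tx`, `ty`; rows at the CoM itself are 0.
#' @export
template_field <- function(template, x, y) {
  dx <- x - template$com[1]
  dy <- y - template$com[2]
  rho <- sqrt(dx^2 + dy^2)
  ok <- rho > 1e-12
  rx <- ifelse(ok, dx / rho, 0)
  ry <- ifelse(ok, dy / rho, 0)
  tx <- cos(template$phi) * rx + sin(template$phi) * (-ry)
  ty <- cos(template$phi) * ry + sin(template$phi) * rx
  cbind(tx = tx, ty = ty)
}

#' @export
print.mst_template <- function(x, ...) {
  cat(sprintf("<mst_template> phi = %.3f, CoM (%.3g, %.3g), spirality %.3f, %s\n",
              x$phi, x$com[1], x$com[2], x$spirality,
              if (x$orientation > 0) "CCW" else if (x$orientation < 0) "CW"
              else "radial"))
  invisible(x)
}

#' Enumerate the MSTd template bank
#'
#' Full cross-product of a uniform pattern-angle grid over `[0, 2*pi)`
#' with a rectangular CoM grid. The default 23 pattern angles and 25 x 20
#' CoM sites give 11500 units. The CoM grid spans `com_span` times the
#' half-extent of the field of view in each dimension (default 1.5), so
#' that centers of motion falling outside the retinal projection plane are
#' still represented; templates with far-outside CoMs present only near-
#' uniform laminar motion inside the display and match poorly, so they are
#' harmless competitors.
#'
#' @param camera An [camera_model()]; sizes the CoM grid.
#' @param n_pattern Number of pattern angles.
#' @param n_x,n_y CoM grid sizes.
#' @param com_span CoM grid half-extent as a multiple of the field-of-view
#'   half-extent (in image units); length 1 or 2 (horizontal, vertical).
#'   The default is wide horizontally (the focus of expansion drifts
#'   horizontally in the emulated displays) and narrower vertically, where
#'   ground-plane centers of motion stay near the horizon and extreme
#'   vertical CoMs would only alias rotational (laminar) flow.
#' @return An object of class `mst_bank`: a list with `units` (data frame
#'   of `phi`, `cx`, `cy`, `spirality`, `orientation`, `com_index`), the
#'   CoM site table, and grid metadata. `n_units = n_pattern * n_x * n_y`.
#' @examples
#' bank <- build_template_bank(n_pattern = 3, n_x = 2, n_y = 2)
#' bank$n_units
#' @export
build_template_bank <- function(camera = camera_model(), n_pattern = 23,
                                n_x = 25, n_y = 20,
                                com_span = c(1.5, 0.75)) {
  if (n_pattern < 1 || n_x < 1 || n_y < 1) {
    stop("grid sizes must be at least 1", call. = FALSE)
  }
  com_span <- rep_len(com_span, 2L)
  f <- camera$focal_length
  half_x <- com_span[1] * f * tan(deg2rad(camera$fov_h) / 2)
  half_y <- com_span[2] * f * tan(deg2rad(camera$fov_v) / 2)
  cx <- if (n_x == 1) 0 else seq(-half_x, half_x, length.out = n_x)
  cy <- if (n_y == 1) 0 else seq(-half_y, half_y, length.out = n_y)
  phi <- seq(0, 2 * pi, length.out = n_pattern + 1)[seq_len(n_pattern)]
  com <- expand.grid(cx = cx, cy = cy, KEEP.OUT.ATTRS = FALSE)
  n_com <- nrow(com)
  units <- data.frame(
    phi = rep(phi, times = n_com),
    com_index = rep(seq_len(n_com), each = n_pattern)
  )
  units$cx <- com$cx[units$com_index]
  units$cy <- com$cy[units$com_index]
  s <- sin(units$phi)
  units$spirality <- abs(s)
  units$orientation <- ifelse(abs(s) < 1e-12, 0L, as.integer(sign(s)))
  structure(
    list(units = units, com = as.matrix(com), n_units = nrow(units),
         n_pattern = n_pattern, n_x = n_x, n_y = n_y,
         n_com = n_com, com_span = com_span),
    class = "mst_bank"
  )
}

#' @export
print.mst_bank <- function(x, ...) {
  cat(sprintf("<mst_bank> %d units = %d pattern angles x %d x %d CoM sites\n",
              x$n_units, x$n_pattern, x$n_x, x$n_y))
  invisible(x)
}
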