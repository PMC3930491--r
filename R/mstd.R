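#' MSTd model parameters
#'
#' Constants of the shunting recurrent competitive field and its input
#' stages. The network constants follow the simulation values used
#' throughout: `A = 1` (inverse membrane time constant), `D = 3.25`
#' (passive decay), `U = 1` (activation upper bound), `W = 2.5` (strength
#' of the spatial competition), `gamma = 0.01` (presynaptic threshold),
#' `beta = 0.07` (sigmoid shape).
#'
#' @param A Inverse cell time constant (1/s), > 0.
#' @param D Passive decay rate, >= 0.
#' @param U Activation upper bound, > 0.
#' @param W Weight of the spatial (across-CoM) inhibition pool, >= 0.
#' @param gamma Presynaptic threshold applied to the feedforward match
#'   input, >= 0.
#' @param gamma_r Threshold of the transfer function where it is applied
#'   to recurrent (activity) signals; units whose activation stays below
#'   it neither self-excite nor inhibit others. Defaults to 0.08.
#' @param beta Sigmoid shape parameter, >= 0.
#' @param sigma_d Decay constant (degrees of visual angle) of the
#'   exponential distance weighting in the template match.
#' @param gain Gain `g` of the extra-retinal eye-velocity field; 1 means
#'   full-speed compensation of pursuit rotation.
#' @param dt_substeps Euler integration substeps per flow frame.
#' @param pool_scale How recurrent inhibition pools are aggregated:
#'   `"mean"` (each pool's transferred activity averaged over the pool, the
#'   default, which keeps the three pool terms on a common O(1) scale
#'   independent of bank size) or `"sum"` (raw sums).
#' @param lesions Named logical vector over
#'   `c("spiral_space", "orientation", "spatial")`; `TRUE` silences that
#'   inhibition pool. See [lesion()].
#' @return An object of class `mst_params`.
#' @export
model_params <- function(A = 1.0, D = 3.25, U = 1.0, W = 2.5,
                         gamma = 0.01, gamma_r = 0.08, beta = 0.07,
                         sigma_d = 5, gain = 1, dt_substeps = 10,
                         pool_scale = c("sum", "mean"),
                         lesions = c(spiral_space = FALSE,
                                     orientation = FALSE,
                                     spatial = FALSE)) {
  pool_scale <- match.arg(pool_scale)
  if (A <= 0 || U <= 0) stop("`A` and `U` must be positive", call. = FALSE)
  if (D < 0 || W < 0 || gamma < 0 || gamma_r < 0 || beta < 0 ||
      sigma_d < 0) {
    stop("`D`, `W`, `gamma`, `gamma_r`, `beta`, `sigma_d` must be ",
         "non-negative", call. = FALSE)
  }
  if (dt_substeps < 1) stop("`dt_substeps` must be >= 1", call. = FALSE)
  stopifnot(identical(sort(names(lesions)),
                      sort(c("spiral_space", "orientation", "spatial"))))
  structure(
    list(A = A, D = D, U = U, W = W, gamma = gamma, gamma_r = gamma_r,
         beta = beta, sigma_d = sigma_d, gain = gain,
         dt_substeps = as.integer(dt_substeps), pool_scale = pool_scale,
         lesions = lesions[c("spiral_space", "orientation", "spatial")]),
    class = "mst_params"
  )
}

#' Lesion (or restore) a competitive interaction pool
#'
#' Zeroes the contribution of one of the three recurrent inhibition pools:
#' `"spiral_space"` (same CoM and orientation, different spirality),
#' `"orientation"` (same CoM, opposite CW/CCW orientation), or
#' `"spatial"` (different CoM). Restoring a lesioned pool returns the
#' parameters to their exact original state.
#'
#' @param params An [model_params()] object.
#' @param pool_name One of `"spiral_space"`, `"orientation"`, `"spatial"`.
#' @param value `TRUE` to lesion (default), `FALSE` to restore.
#' @return The modified `mst_params`.
#' @export
lesion <- function(params, pool_name, value = TRUE) {
  if (!pool_name %in% names(params$lesions)) {
    stop("unknown pool name: ", pool_name, call. = FALSE)
  }
  params$lesions[[pool_name]] <- isTRUE(value)
  params
}

#' Sigmoidal transfer function of the MSTd network
#'
#' Quadratic Naka-Rushton signal function applied to both the feedforward
#' match input and the recurrent activity:
#' \deqn{f(x) = \frac{[x - \Gamma]_+^2}{\beta^2 + [x - \Gamma]_+^2}}
#' with half-wave rectification `[.]_+`. It is 0 at and below the
#' threshold `gamma`, reaches 1/2 at `gamma + beta`, and saturates at 1.
#'
#' @param x Input (vectorized).
#' @param gamma Threshold. @param beta Shape parameter.
#' @return Transferred values in `[0, 1)`.
#' @export
transfer <- function(x, gamma = 0.01, beta = 0.07) {
  h <- pmax(x - gamma, 0)
  h2 <- h * h
  h2 / (beta * beta + h2)
}

#' Extra-retinal eye-velocity gain field
#'
#' Adds, at every flow sample site, `gain` times the first-order rotational
#' flow of the negated eye rotation (translation set to zero). With
#' `gain = 1` this exactly cancels the rotational flow component introduced
#' by a smooth-pursuit eye movement.
#'
#' @param pooled_flow An `mst_flow` (typically the MT output).
#' @param eye_rate Pursuit yaw rate in rad/s (positive toward +X).
#' @param gain Compensation gain `g`.
#' @param camera The [camera_model()].
#' @return The modulated `mst_flow`.
#' @export
apply_gain_field <- function(pooled_flow, eye_rate, gain = 1,
                             camera = camera_model()) {
  if (eye_rate == 0 || gain == 0 || pooled_flow$n_visible == 0L) {
    return(pooled_flow)
  }
  comp <- lhp_flow(pooled_flow$x, pooled_flow$y,
                   Z = rep(1, pooled_flow$n_visible),
                   Tc = c(0, 0, 0), om = c(0, -eye_rate, 0),
                   f = camera$focal_length)
  pooled_flow$u <- pooled_flow$u + gain * comp$u
  pooled_flow$v <- pooled_flow$v + gain * comp$v
  pooled_flow
}

#' Match score between a flow field and one spiral template
#'
#' Cosine-similarity template match with exponential distance weighting:
#' \deqn{S = \frac{1}{N} \sum_i e^{-d_i/\sigma_d}
#'   \left\langle \frac{F_i}{\lVert F_i\rVert}, T(p_i) \right\rangle}
#' where `d_i` is the image distance from sample `i` to the template CoM
#' and `N` the number of visible dots. Zero-length flow vectors and
#' samples exactly at the CoM contribute 0. `|S| <= 1` always.
#'
#' @param pooled_flow An `mst_flow` with at least one sample.
#' @param template An [make_template()] template.
#' @param sigma_d Distance-weighting decay in degrees of visual angle.
#' @param camera The [camera_model()].
#' @return Scalar match score.
#' @export
match_score <- function(pooled_flow, template, sigma_d = 20,
                        camera = camera_model()) {
  n <- pooled_flow$n_visible
  if (n == 0L) stop("match score undefined for an empty flow field",
                    call. = FALSE)
  tf <- template_field(template, pooled_flow$x, pooled_flow$y)
  nrm <- sqrt(pooled_flow$u^2 + pooled_flow$v^2)
  ok <- nrm > 1e-12
  fu <- ifelse(ok, pooled_flow$u / nrm, 0)
  fv <- ifelse(ok, pooled_flow$v / nrm, 0)
  d <- sqrt((pooled_flow$x - template$com[1])^2 +
            (pooled_flow$y - template$com[2])^2)
  w <- exp(-d / deg2iu(sigma_d, camera))
  sum(w * (fu * tf[, "tx"] + fv * tf[, "ty"])) / n
}

# Match scores of every bank unit against one pooled flow field.
# The spiral template is a fixed linear combination of the radial and
# center basis fields, so per CoM site only two weighted projections are
# needed; every pattern angle is then a cosine/sine combination of those.
bank_match_scores <- function(pooled_flow, bank, sigma_d = 20,
                              camera = camera_model()) {
  n <- pooled_flow$n_visible
  if (n == 0L) return(numeric(bank$n_units))
  nrm <- sqrt(pooled_flow$u^2 + pooled_flow$v^2)
  ok <- nrm > 1e-12
  fu <- ifelse(ok, pooled_flow$u / nrm, 0)
  fv <- ifelse(ok, pooled_flow$v / nrm, 0)
  sd_iu <- deg2iu(sigma_d, camera)
  dx <- outer(pooled_flow$x, bank$com[, 1], "-")
  dy <- outer(pooled_flow$y, bank$com[, 2], "-")
  rho <- sqrt(dx^2 + dy^2)
  w <- exp(-rho / sd_iu)
  w[rho <= 1e-12] <- 0
  rho[rho <= 1e-12] <- 1
  rx <- dx / rho
  ry <- dy / rho
  radial <- colSums(w * (fu * rx + fv * ry)) / n
  center <- colSums(w * (fv * rx - fu * ry)) / n
  unname(cos(bank$units$phi) * radial[bank$units$com_index] +
         sin(bank$units$phi) * center[bank$units$com_index])
}
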