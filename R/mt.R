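#' MT pooling parameters
#'
#' Model MT spatially pools the V1 flow vectors component-wise with a
#' truncated Gaussian receptive-field kernel evaluated at the dot
#' projection sites themselves (the flow is sparse, so pooling on a dense
#' grid would leave most sites empty).
#'
#' @param kernel_sigma Gaussian kernel width in degrees of visual angle.
#' @param kernel_radius Truncation radius in degrees (>= `kernel_sigma`).
#' @return An object of class `mst_mt_params`.
#' @export
mt_params <- function(kernel_sigma = 3, kernel_radius = 9) {
  if (kernel_radius < kernel_sigma) {
    stop("`kernel_radius` must be at least `kernel_sigma`", call. = FALSE)
  }
  structure(list(kernel_sigma = kernel_sigma, kernel_radius = kernel_radius),
            class = "mst_mt_params")
}

#' Gaussian spatial pooling of a flow field (model MT)
#'
#' Each output vector is the normalized Gaussian-weighted mean of the input
#' vectors within `kernel_radius` of that site, component-wise. Sample
#' locations are identical to the input's. An empty flow field is returned
#' unchanged with a warning and attribute `empty = TRUE`.
#'
#' @param flow An `mst_flow`.
#' @param params An [mt_params()].
#' @param camera The [camera_model()] used to convert degrees to
#'   image-plane units.
#' @return An `mst_flow` with pooled `u`, `v`.
#' @export
pool_flow <- function(flow, params = mt_params(), camera = camera_model()) {
  if (flow$n_visible == 0L) {
    warning("empty flow field; nothing to pool", call. = FALSE)
    attr(flow, "empty") <- TRUE
    return(flow)
  }
  sigma <- deg2iu(params$kernel_sigma, camera)
  radius <- deg2iu(params$kernel_radius, camera)
  dx <- outer(flow$x, flow$x, "-")
  dy <- outer(flow$y, flow$y, "-")
  d2 <- dx^2 + dy^2
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > radius^2] <- 0
  w <- w / rowSums(w)  # self-weight 1 guarantees a positive row sum
  flow$u <- as.vector(w %*% flow$u)
  flow$v <- as.vector(w %*% flow$v)
  flow
}
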