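#' Default run configuration
#'
#' Nested list of every tunable of the pipeline, with the simulation
#' defaults baked in: camera geometry, scene composition, trial timing,
#' the MSTd network constants, and experiment settings. [load_config()]
#' validates user files against this structure.
#'
#' @return A named nested list of class `mst_config`.
#' @export
default_config <- function() {
  structure(list(
    camera = list(focal_length = 1, fov_h = 110, fov_v = 94,
                  frame_rate = 60),
    scene = list(kind = "ground_plane", n_dots = 200,
                 depth_range = c(1.4, 25), eye_height = 1.6),
    trajectory = list(radius = 12, lambda = 1, speed = 2,
                      gaze_condition = "gaze_along_heading", frames = 60,
                      target_arc = NULL, target_offset_deg = 10),
    model = list(A = 1.0, D = 3.25, U = 1.0, W = 2.5, gamma = 0.01,
                 gamma_r = 0.08, beta = 0.07, sigma_d = 5, gain = 1,
                 dt_substeps = 10, pool_scale = "sum",
                 lesions = list(spiral_space = FALSE, orientation = FALSE,
                                spatial = FALSE)),
    bank = list(n_pattern = 23, n_x = 25, n_y = 20, com_span = c(1.5, 0.75)),
    mt = list(kernel_sigma = 3, kernel_radius = 9),
    experiment = list(radii = c(9, 14, 15), reps = 20, seed = 1),
    seed = 1
  ), class = "mst_config")
}

check_keys <- function(user, ref, path = "") {
  if (!is.list(user)) return(invisible())
  bad <- setdiff(names(user), names(ref))
  if (length(bad)) {
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      check_keys(user[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible()
}

merge_config <- function(user, ref) {
  for (nm in names(user)) {
    val <- if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
               is.list(user[[nm]])) {
      merge_config(user[[nm]], ref[[nm]])
    } else {
      user[[nm]]
    }
    ref[nm] <- list(val)  # preserves NULL values
  }
  ref
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON; YAML is a superset) configuration file, rejects
#' unknown keys with a field-path diagnostic, and fills every missing
#' field from [default_config()]. An empty file yields the full default
#' configuration.
#'
#' @param path Path to the configuration file.
#' @return An `mst_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- default_config()
  check_keys(user, ref)
  cfg <- merge_config(user, unclass(ref))
  structure(cfg, class = "mst_config")
}

#' Save a run configuration
#'
#' @param config An `mst_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Model parameters from a configuration
#'
#' @param config An `mst_config`.
#' @return An [model_params()] object.
#' @export
config_params <- function(config) {
  m <- config$model
  model_params(A = m$A, D = m$D, U = m$U, W = m$W, gamma = m$gamma,
               gamma_r = m$gamma_r, beta = m$beta, sigma_d = m$sigma_d,
               gain = m$gain,
               dt_substeps = m$dt_substeps, pool_scale = m$pool_scale,
               lesions = unlist(m$lesions))
}

#' Camera from a configuration
#'
#' @param config An `mst_config`.
#' @return An [camera_model()] object.
#' @export
config_camera <- function(config) {
  do.call(camera_model, config$camera)
}
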