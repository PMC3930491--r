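# Orientation congruence of the spiral readout with the travel direction.
# Under the default display and matching parameters, gaze-along-heading
# travel on a CCW path (lambda = +1) drives its sustained activity peak
# onto CCW-orientation templates (mirror-symmetrically, CW paths onto CW
# templates), so signed spiralities are mapped into curvature-aligned
# units as lambda * signed_spirality: positive values mean spirality
# congruent with the traversal direction.
aligned_spirality <- function(signed_spirality, lambda) {
  lambda * signed_spirality
}

# True heading azimuth (deg, camera frame) at the final frame.
true_heading_azimuth <- function(trajectory) {
  st <- trajectory_state(trajectory, trajectory$t[trajectory$frames])
  psi <- st$yaw
  right <- c(cos(psi), 0, -sin(psi))
  fwd <- c(sin(psi), 0, cos(psi))
  rad2deg(atan2(sum(st$T * right), sum(st$T * fwd)))
}

#' Signed path error between a trial and its calibration trial
#'
#' The model's path estimate is the curvature-aligned peak spirality; path
#' error is the difference between a condition trial and the
#' gaze-along-heading calibration trial at the same radius and traversal
#' direction. Positive errors are overestimations of path curvature,
#' negative errors underestimations.
#'
#' @param condition_result,calibration_result One-row trial results (as in
#'   the `trials` table of [run_gaze_experiment()]), with fields `radius`,
#'   `lambda`, `spirality_signed`.
#' @return Signed path error (spirality units).
#' @export
path_error <- function(condition_result, calibration_result) {
  if (!isTRUE(all.equal(condition_result$radius,
                        calibration_result$radius)) ||
      condition_result$lambda != calibration_result$lambda) {
    stop("condition and calibration trials must share radius and direction",
         call. = FALSE)
  }
  aligned_spirality(condition_result$spirality_signed,
                    condition_result$lambda) -
    aligned_spirality(calibration_result$spirality_signed,
                      calibration_result$lambda)
}

#' Signed heading error of a trial
#'
#' Estimated heading azimuth minus the true final-frame heading azimuth,
#' signed into path-curvature coordinates: positive errors are biased in
#' the direction of the path curvature (toward the inside of the path),
#' negative errors opposite to it.
#'
#' @param trial_result One-row trial result with field `heading_az` (deg).
#' @param trajectory The trial's `mst_trajectory`.
#' @return Signed heading error in degrees.
#' @export
heading_error <- function(trial_result, trajectory) {
  if (is.na(trial_result$heading_az)) {
    stop("no heading estimate in trial result", call. = FALSE)
  }
  d <- trajectory$descriptor
  lam <- if (d$type == "straight") 1 else d$lambda
  -lam * (trial_result$heading_az - true_heading_azimuth(trajectory))
}

# One seeded trial of a circular-path condition; returns readouts.
# `variants` is a named list of mst_params; match scores are computed once
# and integrated per variant (used by the lesion study).
run_condition_trial <- function(scene, condition, r, lambda, omega, frames,
                                frame_rate, camera, variants, bank) {
  traj <- make_circular_trajectory(
    r = r, lambda = lambda, omega = omega, gaze_condition = condition,
    frames = frames, frame_rate = frame_rate,
    eye_height = scene$eye_height
  )
  S <- trial_scores(scene, traj, camera, variants[[1]], bank)
  true_az <- true_heading_azimuth(traj)
  out <- lapply(variants, function(p) {
    z <- integrate_scores(S, bank, p, frame_rate)
    act <- structure(list(z = z, bank = bank), class = "mst_activity")
    sp <- readout_curvature(act)
    hd <- readout_heading(act, camera)
    list(spirality_signed = sp,
         heading_az = hd[["azimuth"]],
         heading_error = -lambda * (hd[["azimuth"]] - true_az))
  })
  out
}

summarize_trials <- function(trials) {
  sem <- function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                     else NA_real_
  agg <- function(v) {
    m <- stats::aggregate(trials[[v]],
                          by = trials[c("variant", "condition", "radius")],
                          FUN = mean)
    s <- stats::aggregate(trials[[v]],
                          by = trials[c("variant", "condition", "radius")],
                          FUN = sem)
    names(m)[4] <- paste0("mean_", v)
    m[[paste0("sem_", v)]] <- s$x
    m
  }
  out <- merge(agg("path_error"), agg("heading_error"),
               by = c("variant", "condition", "radius"), sort = TRUE)
  out[order(out$variant, out$radius, out$condition), ]
}

# Shared engine for the gaze-style experiments: a grid of
# radius x condition x rep seeded trials, path errors computed against the
# same-rep, same-radius gaze-along-heading calibration trial, for one or
# more parameter variants sharing the flow and match-score computation.
gaze_grid_run <- function(radii, conditions, reps, seed, variants,
                          speed = 2, n_dots = 200, frames = 60,
                          frame_rate = 60, lambda = 1,
                          depth_range = c(1.4, 25), eye_height = 1.6,
                          camera = camera_model(), bank = NULL,
                          calibration_condition = "gaze_along_heading") {
  if (!calibration_condition %in% conditions) {
    stop("`conditions` must include the calibration condition ",
         calibration_condition, call. = FALSE)
  }
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (is.null(bank)) bank <- build_template_bank(camera)
  rows <- list()
  counter <- 0L
  for (r in radii) {
    omega <- speed / r
    for (rep in seq_len(reps)) {
      counter <- counter + 1L
      trial_seed <- fanout_seed(seed, counter)
      scene <- make_scene("ground_plane", n_dots = n_dots,
                          depth_range = depth_range,
                          eye_height = eye_height, seed = trial_seed,
                          camera = camera)
      per_cond <- lapply(conditions, function(cond) {
        run_condition_trial(scene, cond, r, lambda, omega, frames,
                            frame_rate, camera, variants, bank)
      })
      names(per_cond) <- conditions
      for (vn in names(variants)) {
        cal <- per_cond[[calibration_condition]][[vn]]
        for (cond in conditions) {
          res <- per_cond[[cond]][[vn]]
          rows[[length(rows) + 1L]] <- data.frame(
            variant = vn, condition = cond, radius = r, lambda = lambda,
            rep = rep, seed = trial_seed,
            spirality_signed = res$spirality_signed,
            path_error =
              aligned_spirality(res$spirality_signed, lambda) -
              aligned_spirality(cal$spirality_signed, lambda),
            heading_az = res$heading_az,
            heading_error = res$heading_error
          )
        }
      }
    }
  }
  trials <- do.call(rbind, rows)
  structure(
    list(trials = trials, summary = summarize_trials(trials),
         radii = radii, conditions = conditions, reps = reps, seed = seed,
         speed = speed, n_dots = n_dots, frames = frames,
         frame_rate = frame_rate, lambda = lambda),
    class = "mst_report"
  )
}

#' @export
print.mst_report <- function(x, ...) {
  cat(sprintf("<mst_report> %d trials (%d radii x %d conditions x %d reps)\n",
              nrow(x$trials), length(x$radii), length(x$conditions),
              x$reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Circular-path gaze experiment
#'
#' Simulates travel along circular paths under the five gaze conditions
#' (`z_axis`, `outside_path`, `on_path`, `inside_path`,
#' `gaze_along_heading`), each radius x condition x rep trial on a fresh
#' seeded 200-dot ground plane, and reports signed path and heading errors
#' against the same-trial gaze-along-heading calibration. Within a rep the
#' same scene is shared across conditions (a paired design; only the gaze
#' geometry differs, as in the displays being emulated).
#'
#' @param radii Path radii in meters.
#' @param conditions Gaze conditions; must include `gaze_along_heading`.
#' @param reps Replicates per radius (fresh dot layouts).
#' @param seed Base seed; per-trial seeds fan out deterministically.
#' @param speed Translation speed (m/s); the angular rate is `speed / r`.
#' @param n_dots,frames,frame_rate,lambda Display parameters.
#' @param camera,params,bank Model configuration; the bank defaults to the
#'   full 11500-unit bank, built once and shared.
#' @return An `mst_report` with per-trial results (`$trials`) and
#'   mean/SEM aggregates (`$summary`).
#' @export
run_gaze_experiment <- function(radii = c(9, 14, 15),
                                conditions = gaze_conditions,
                                reps = 20, seed = 1, speed = 2,
                                n_dots = 200, frames = 60, frame_rate = 60,
                                lambda = 1, camera = camera_model(),
                                params = model_params(), bank = NULL) {
  gaze_grid_run(radii, conditions, reps, seed,
                variants = list(intact = params), speed = speed,
                n_dots = n_dots, frames = frames, frame_rate = frame_rate,
                lambda = lambda, camera = camera, bank = bank)
}

#' Smooth-pursuit experiment
#'
#' Runs the two pursuit conditions: `orient_along_heading` (body
#' orientation along heading, pursuit toward the path exterior) and
#' `orient_along_z` (body orientation fixed, pursuit toward the interior).
#' The two conditions share identical retinal kinematics by construction;
#' they differ only in the extra-retinal pursuit signal that the MSTd gain
#' field compensates. Path errors are computed against gaze-along-heading
#' calibration trials.
#'
#' @inheritParams run_gaze_experiment
#' @return An `mst_report`.
#' @export
run_pursuit_experiment <- function(radii = c(9, 14, 15), reps = 20, seed = 1,
                                   speed = 2, n_dots = 200, frames = 60,
                                   frame_rate = 60, lambda = 1,
                                   camera = camera_model(),
                                   params = model_params(), bank = NULL) {
  gaze_grid_run(radii,
                conditions = c("orient_along_heading", "orient_along_z",
                               "gaze_along_heading"),
                reps = reps, seed = seed,
                variants = list(intact = params), speed = speed,
                n_dots = n_dots, frames = frames, frame_rate = frame_rate,
                lambda = lambda, camera = camera, bank = bank)
}

#' Simulated-rotation heading experiment
#'
#' Straight travel toward two fronto-parallel random-dot planes with an
#' added simulated rotation, emulating displays in which fixating subjects
#' misperceive a curved path. Heading bias (estimated minus true final
#' heading azimuth, positive in the rotation direction) is reported per
#' rotation rate, with a least-squares hyperbolic-tangent fit
#' `a * tanh(b * rate)` across rates.
#'
#' The visuotopic grid of the default template bank is tailored to path
#' spirality and is too coarse (about 10 degrees) to resolve degree-scale
#' heading biases, so this protocol uses a finer, narrower center-of-motion
#' grid concentrated around the display center (23 pattern angles x
#' `n_x` x `n_y` sites over `span_deg` degrees).
#'
#' @param rates_deg Simulated rotation rates in deg/s (symmetric about 0).
#' @param reps Replicates per rate.
#' @param seed Base seed.
#' @param speed Translation speed (m/s).
#' @param n_dots Total dots across the two planes.
#' @param plane_depths Depths of the two planes (m).
#' @param frames,frame_rate Trial timing.
#' @param span_deg,n_x,n_y Heading-bank geometry (half-span in degrees and
#'   grid sizes).
#' @param camera,params Model configuration. The default parameters widen
#'   the match distance weighting to 12 degrees: the two-plane display
#'   spreads its dots over the whole field, so the ground-plane default
#'   of 5 degrees would leave too few dots near any center of motion.
#' @return List with `table` (rate, mean bias, sem), `trials`, `fit`
#'   (from [fit_tanh()]), and `grid_step_deg` (azimuth resolution).
#' @export
run_simulated_rotation <- function(rates_deg = -5:5, reps = 5, seed = 1,
                                   speed = 2, n_dots = 220,
                                   plane_depths = c(10, 20), frames = 60,
                                   frame_rate = 60, span_deg = 40,
                                   n_x = 41, n_y = 5,
                                   camera = camera_model(),
                                   params = model_params(sigma_d = 12)) {
  if (!isTRUE(all.equal(sort(rates_deg), sort(-rates_deg)))) {
    stop("`rates_deg` must be symmetric about 0", call. = FALSE)
  }
  f <- camera$focal_length
  span_iu <- f * tan(deg2rad(span_deg))
  fov_half_x <- f * tan(deg2rad(camera$fov_h) / 2)
  bank <- build_template_bank(camera, n_pattern = 23, n_x = n_x, n_y = n_y,
                              com_span = span_iu / fov_half_x)
  # vertical extent rescaled to the same angular span
  rows <- list()
  counter <- 0L
  for (rep in seq_len(reps)) {
    counter <- counter + 1L
    sseed <- fanout_seed(seed, counter)
    scene <- make_scene("frontoparallel_planes", n_dots = n_dots,
                        plane_depths = plane_depths, seed = sseed,
                        camera = camera)
    for (rho in rates_deg) {
      traj <- make_straight_rotation_trajectory(
        speed = speed, rotation_rate = deg2rad(rho), frames = frames,
        frame_rate = frame_rate, eye_height = scene$eye_height
      )
      act <- run_trial(scene, traj, camera, params, bank)
      est <- readout_heading(act, camera)[["azimuth"]]
      bias <- est - true_heading_azimuth(traj)
      rows[[length(rows) + 1L]] <- data.frame(
        rate_deg = rho, rep = rep, seed = sseed, bias_deg = bias)
    }
  }
  trials <- do.call(rbind, rows)
  tab <- stats::aggregate(bias_deg ~ rate_deg, data = trials, FUN = mean)
  names(tab)[2] <- "mean_bias_deg"
  tab$sem_bias_deg <- stats::aggregate(
    bias_deg ~ rate_deg, data = trials,
    FUN = function(x) if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                      else NA_real_)$bias_deg
  fit <- tryCatch(fit_tanh(tab$rate_deg, tab$mean_bias_deg),
                  error = function(e) {
                    warning("tanh fit failed: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
  grid_step <- iu2deg(2 * span_iu / (n_x - 1), camera)
  list(table = tab, trials = trials, fit = fit,
       grid_step_deg = grid_step)
}

#' Circular-sled experiment
#'
#' Passive circular translation inside a dot-covered room with gaze fixed
#' in the world (no body or eye rotation), the paradigm used to probe
#' "path cells". Returns the curvature-aligned peak spirality as a
#' function of the angular rate around the track; at slow rates the peak
#' sits on radial expansion (zero spirality) and at fast rates the
#' temporally accumulated, distance-weighted input shifts it onto spiral
#' templates, with opposite template orientations for CW versus CCW
#' traversal.
#'
#' Trial duration shrinks at fast rates so that no trial exceeds a
#' quarter-circle traversal; the frame count stays fixed.
#'
#' @param angular_rates_deg Rates around the track in deg/s (> 0).
#' @param seed Base seed.
#' @param reps Replicates per rate and direction.
#' @param radius Track radius (m).
#' @param n_dots Dots on the room walls.
#' @param directions Traversal directions to run (`+1` CCW, `-1` CW).
#' @param frames Frames per trial.
#' @param max_duration Longest trial duration in seconds.
#' @param camera,params,bank Model configuration; as in
#'   [run_simulated_rotation()], the default parameters widen the match
#'   distance weighting for the full-field room display.
#' @return List with `table` (rate, lambda, mean aligned spirality),
#'   `trials`, and `threshold_rate_deg`, the smallest rate whose mean
#'   |spirality| leaves zero.
#' @export
run_sled_experiment <- function(angular_rates_deg = c(2, 5, 10, 20, 40, 80),
                                seed = 1, reps = 3, radius = 1,
                                n_dots = 300, directions = c(1, -1),
                                frames = 60, max_duration = 1,
                                camera = camera_model(),
                                params = model_params(sigma_d = 12),
                                bank = NULL) {
  if (any(angular_rates_deg <= 0)) {
    stop("`angular_rates_deg` must be positive", call. = FALSE)
  }
  if (is.null(bank)) bank <- build_template_bank(camera)
  rows <- list()
  counter <- 0L
  for (rep in seq_len(reps)) {
    counter <- counter + 1L
    sseed <- fanout_seed(seed, counter)
    scene <- make_scene("room_walls", n_dots = n_dots, seed = sseed,
                        camera = camera)
    for (rate in angular_rates_deg) {
      omega <- deg2rad(rate)
      duration <- min(max_duration, deg2rad(85) / omega)
      fr_rate <- frames / duration
      for (lam in directions) {
        traj <- make_circular_trajectory(
          r = radius, lambda = lam, omega = omega,
          gaze_condition = "z_axis", frames = frames,
          frame_rate = fr_rate, eye_height = scene$eye_height
        )
        act <- run_trial(scene, traj, camera, params, bank)
        sp <- readout_curvature(act)
        rows[[length(rows) + 1L]] <- data.frame(
          rate_deg = rate, lambda = lam, rep = rep, seed = sseed,
          spirality_signed = sp,
          spirality_aligned = aligned_spirality(sp, lam))
      }
    }
  }
  trials <- do.call(rbind, rows)
  tab <- stats::aggregate(spirality_aligned ~ rate_deg + lambda,
                          data = trials, FUN = mean)
  names(tab)[3] <- "mean_spirality_aligned"
  nonzero <- tab$rate_deg[abs(tab$mean_spirality_aligned) > 0]
  list(table = tab[order(tab$lambda, tab$rate_deg), ], trials = trials,
       threshold_rate_deg = if (length(nonzero)) min(nonzero) else NA_real_)
}

#' Dot-density sweep
#'
#' Repeats the gaze experiment at several scene dot counts and reports the
#' *path-error deviation*: the per-condition, per-radius mean path error at
#' each count minus the 200-dot reference.
#'
#' @param dot_counts Scene dot counts; 200 is added if absent.
#' @inheritParams run_gaze_experiment
#' @return List with `deviations` (count x condition x radius table),
#'   `reports` (one `mst_report` per count), and `reference_count`.
#' @export
run_density_sweep <- function(dot_counts = c(25, 50, 100, 200, 300),
                              radii = c(9, 14, 15),
                              conditions = gaze_conditions,
                              reps = 10, seed = 1, speed = 2, frames = 60,
                              frame_rate = 60, lambda = 1,
                              camera = camera_model(),
                              params = model_params(), bank = NULL) {
  if (any(dot_counts < 1)) stop("`dot_counts` must be >= 1", call. = FALSE)
  ref <- 200L
  dot_counts <- sort(unique(c(as.integer(dot_counts), ref)))
  if (is.null(bank)) bank <- build_template_bank(camera)
  reports <- lapply(dot_counts, function(n) {
    run_gaze_experiment(radii = radii, conditions = conditions, reps = reps,
                        seed = seed, speed = speed, n_dots = n,
                        frames = frames, frame_rate = frame_rate,
                        lambda = lambda, camera = camera, params = params,
                        bank = bank)
  })
  names(reports) <- as.character(dot_counts)
  ref_sum <- reports[[as.character(ref)]]$summary
  dev <- do.call(rbind, lapply(dot_counts, function(n) {
    s <- reports[[as.character(n)]]$summary
    m <- merge(s[, c("condition", "radius", "mean_path_error")],
               ref_sum[, c("condition", "radius", "mean_path_error")],
               by = c("condition", "radius"),
               suffixes = c("", "_ref"))
    data.frame(n_dots = n, condition = m$condition, radius = m$radius,
               deviation = m$mean_path_error - m$mean_path_error_ref)
  }))
  list(deviations = dev[order(dev$n_dots, dev$radius, dev$condition), ],
       reports = reports, reference_count = ref)
}

# Sign/rank pattern of human path judgments, per radius: underestimation
# in z_axis, outside_path and on_path, overestimation in inside_path, and
# |z_axis| >= |on_path|.
pattern_reproduced <- function(summary_df, variant = "intact") {
  s <- summary_df[summary_df$variant == variant, ]
  ok <- TRUE
  for (r in unique(s$radius)) {
    m <- function(cond) s$mean_path_error[s$condition == cond &
                                          s$radius == r]
    ok <- ok && m("z_axis") < 0 && m("outside_path") < 0 &&
      m("on_path") < 0 && m("inside_path") > 0 &&
      abs(m("z_axis")) >= abs(m("on_path"))
  }
  isTRUE(ok)
}

#' Competition lesion study
#'
#' Repeats the gaze experiment with each of the three recurrent inhibition
#' pools lesioned, reusing the per-trial flow and match-score computation
#' across variants (lesions only change the network integration). For
#' every variant it reports path errors, whether the human sign/rank
#' pattern of path errors is reproduced, and the spread of the
#' inside-path/on-path/gaze-along-heading mean errors (which collapses
#' under the spatial lesion).
#'
#' @inheritParams run_gaze_experiment
#' @return List with `trials`, `summary` (per variant), `pattern`
#'   (named logical per variant), and `convergence_spread` (per variant
#'   mean spread of the inside/on/gaze-along means, in spirality units).
#' @export
run_lesion_study <- function(radii = c(9, 14, 15), reps = 10, seed = 1,
                             speed = 2, n_dots = 200, frames = 60,
                             frame_rate = 60, lambda = 1,
                             camera = camera_model(),
                             params = model_params(), bank = NULL) {
  variants <- list(
    intact = params,
    spiral_space = lesion(params, "spiral_space"),
    orientation = lesion(params, "orientation"),
    spatial = lesion(params, "spatial")
  )
  run <- gaze_grid_run(radii, gaze_conditions, reps, seed, variants,
                       speed = speed, n_dots = n_dots, frames = frames,
                       frame_rate = frame_rate, lambda = lambda,
                       camera = camera, bank = bank)
  pat <- vapply(names(variants), function(v) {
    pattern_reproduced(run$summary, v)
  }, logical(1))
  spread <- vapply(names(variants), function(v) {
    s <- run$summary[run$summary$variant == v &
                     run$summary$condition %in%
                       c("inside_path", "on_path", "gaze_along_heading"), ]
    mean(vapply(split(s$mean_path_error, s$radius),
                function(x) max(x) - min(x), numeric(1)))
  }, numeric(1))
  list(trials = run$trials, summary = run$summary, pattern = pat,
       convergence_spread = spread)
}

#' Least-squares hyperbolic-tangent fit
#'
#' Fits `y = a * tanh(b * x)` by Levenberg-Marquardt least squares with a
#' deterministic initializer (the initial `a` is the largest |y|, the
#' initial `b` matches the central slope). If the response has zero
#' variance the fit is `a = 0` with `r_squared = 1` by convention.
#'
#' @param xs,ys Numeric vectors (at least 4 points).
#' @return `list(a, b, r_squared)`.
#' @export
fit_tanh <- function(xs, ys) {
  if (length(xs) < 4 || length(xs) != length(ys)) {
    stop("need at least 4 (x, y) points", call. = FALSE)
  }
  if (stats::var(ys) == 0) {
    return(list(a = 0, b = 0, r_squared = 1))
  }
  a0 <- max(abs(ys)) * sign(stats::cor(xs, ys))
  if (!is.finite(a0) || a0 == 0) a0 <- max(abs(ys))
  slope <- stats::coef(stats::lm(ys ~ xs))[2]
  b0 <- as.numeric(slope / a0)
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / max(abs(xs))
  fit <- minpack.lm::nlsLM(
    y ~ a * tanh(b * x),
    data = data.frame(x = xs, y = ys),
    start = list(a = a0, b = b0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  resid <- ys - co[["a"]] * tanh(co[["b"]] * xs)
  r2 <- 1 - sum(resid^2) / sum((ys - mean(ys))^2)
  list(a = co[["a"]], b = co[["b"]], r_squared = r2)
}
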