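#' School model configuration
#'
#' Parameters for a school of N self-propelled agents that combine the zonal
#' social direction with an individually sensed light-gradient direction.
#' Each step the desired direction is `d = d_social + w * d_environmental`
#' (both unit vectors, either possibly zero), turn-limited against the
#' current heading, perturbed by the social error, and followed at a speed
#' set by the local light level, `s = s_min + L * (s_max - s_min)` (slow in
#' dark, fast in bright water).
#'
#' The zone radii and speeds are specified in body lengths and converted to
#' cm via `body_length_cm` (default 3.4 cm, the rummy-nose tetra value).
#' `s_min_bls`/`s_max_bls` defaults (0.5 and 3.0 BL/s) are plausible cruising
#' speeds for small schooling fish; they are model choices, not measured
#' values, and all shape-based analyses are insensitive to their exact value.
#'
#' @param n_agents number of agents N.
#' @param w gradient-sensing weight (>= 0); `w = 0` is the purely social
#'   (emergent-sensing) limit.
#' @param sigma_w sd (radians) of the Gaussian error applied to the sensed
#'   gradient direction at each step.
#' @param s_min_bls,s_max_bls speed range in body lengths per second.
#' @param body_length_cm body length in cm.
#' @param social a [social_params()].
#' @param steps number of time steps.
#' @param record_every record every k-th step (must divide `steps`); the
#'   initial state is also recorded.
#' @param seed integer seed for the run.
#' @param gradient_zero_tol gradient magnitudes below this (1/cm) are treated
#'   as zero, so agents deep inside the dark spot fall back on social
#'   information alone.
#' @param env_enabled set `FALSE` to disable the environmental term entirely
#'   (the purely social reference build).
#' @return a `model_config` list.
#' @export
model_config <- function(n_agents = 32, w = 0, sigma_w = 0,
                         s_min_bls = 0.5, s_max_bls = 3.0,
                         body_length_cm = 3.4, social = social_params(),
                         steps = 10000L, record_every = 100L, seed = 1L,
                         gradient_zero_tol = 1e-6, env_enabled = TRUE) {
  cfg <- list(n_agents = as.integer(n_agents), w = w, sigma_w = sigma_w,
              s_min_bls = s_min_bls, s_max_bls = s_max_bls,
              body_length_cm = body_length_cm, social = social,
              steps = as.integer(steps), record_every = as.integer(record_every),
              seed = as.integer(seed), gradient_zero_tol = gradient_zero_tol,
              env_enabled = isTRUE(env_enabled))
  class(cfg) <- "model_config"
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  if (cfg$n_agents < 1) stop("model config: need at least one agent")
  if (cfg$w < 0) stop("model config: w must be >= 0")
  if (cfg$sigma_w < 0) stop("model config: sigma_w must be >= 0")
  if (!(cfg$s_min_bls > 0 && cfg$s_min_bls <= cfg$s_max_bls))
    stop("model config: need 0 < s_min <= s_max")
  if (cfg$steps < 1) stop("model config: steps must be >= 1")
  if (cfg$steps %% cfg$record_every != 0)
    stop("model config: record_every must divide steps")
  validate_social_params(cfg$social)
  invisible(cfg)
}

#' Speed from local light level
#'
#' Linear speed modulation: `s = s_min + L * (s_max - s_min)`, so agents move
#' slowly in dark regions and quickly in bright ones — the rule behind
#' emergent collective gradient sensing.
#'
#' @param L light level(s) in `[0, 1]`.
#' @param s_min,s_max speed range, cm/s.
#' @return speed(s) in cm/s.
#' @export
speed_from_light <- function(L, s_min, s_max) {
  if (any(L < 0 | L > 1)) stop("light level must lie in [0, 1]")
  s_min + L * (s_max - s_min)
}

#' Environmental desired direction
#'
#' The negative light-field gradient at the agent's position, normalised to
#' unit length and rotated by a Gaussian sensing error of sd `sigma_w`.
#' Inside the dark region, where the gradient magnitude falls below `tol`,
#' the zero vector is returned (no gradient to sense) and no error is drawn.
#'
#' @param frame a `field_frame`.
#' @param x agent position, cm.
#' @param sigma_w gradient sensing error sd, radians.
#' @param tol gradient-magnitude threshold, 1/cm.
#' @return a unit 2-vector or the zero vector.
#' @export
environmental_direction <- function(frame, x, sigma_w = 0, tol = 1e-6) {
  g <- -field_gradient(frame, x)
  gn <- sqrt(sum(g^2))
  if (gn < tol) return(c(0, 0))
  g <- g / gn
  if (sigma_w > 0) g <- rotate_vec(g, stats::rnorm(1, 0, sigma_w))
  g
}

#' Combined desired direction
#'
#' `d = d_social + w * d_environmental`.  Both inputs are unit vectors or
#' zero vectors; the result is not normalised.  When both terms are zero the
#' caller keeps the current heading.
#'
#' @param d_social,d_env unit or zero 2-vectors.
#' @param w gradient-sensing weight.
#' @return a 2-vector.
#' @export
desired_direction <- function(d_social, d_env, w) {
  as.numeric(d_social) + w * as.numeric(d_env)
}

#' Initial school state
#'
#' Positions uniform in the central quarter-area box of the arena, headings
#' uniform on the circle.  Uses R's global RNG.
#'
#' @param config a [model_config()].
#' @param arena arena size `c(width, height)` in cm.
#' @return list with `pos` (N x 2) and `heading` (N x 2).
#' @export
init_school <- function(config, arena) {
  n <- config$n_agents
  pos <- cbind(stats::runif(n, 0.25 * arena[1], 0.75 * arena[1]),
               stats::runif(n, 0.25 * arena[2], 0.75 * arena[2]))
  ang <- stats::runif(n, 0, 2 * pi)
  list(pos = pos, heading = cbind(cos(ang), sin(ang)))
}

run_school_cpp <- function(pos, heading, frames, dims, frame_of_step, config,
                           arena, dxy, steps, record_every) {
  bl <- config$body_length_cm
  p <- config$social
  cpp_run_school(pos, heading, frames, as.integer(dims),
                 as.integer(frame_of_step),
                 dxy[["dx"]], dxy[["dy"]], arena[1], arena[2],
                 p$dt_s, config$w, config$sigma_w, config$env_enabled,
                 config$s_min_bls * bl, config$s_max_bls * bl,
                 p$r_repulsion_bl * bl, p$r_orientation_bl * bl,
                 p$r_attraction_bl * bl, cos_half_perception(p),
                 max_turn_rad(p), p$social_error_sd,
                 config$gradient_zero_tol, as.integer(steps),
                 as.integer(record_every))
}

#' Advance a school by one time step
#'
#' A single synchronous update against one light-field frame: social and
#' environmental desired directions, turn limit, social error, speed from the
#' local light level, reflective walls.  Shares the compiled update path with
#' [run_simulation()], so stepping a state manually and running the full loop
#' give identical trajectories for the same RNG state.
#'
#' @param state list with `pos` (N x 2, cm) and `heading` (N x 2, unit rows).
#' @param frame a `field_frame`.
#' @param config a [model_config()].
#' @return the new state (same shape), plus `speed` and `light` per agent.
#' @export
step_school <- function(state, frame, config) {
  nx <- nrow(frame$values); ny <- ncol(frame$values)
  d <- frame_spacing(frame)
  out <- run_school_cpp(state$pos, state$heading,
                        as.numeric(frame$values), c(nx, ny, 1L), 1L,
                        config, frame$arena, d, 1L, 1L)
  keep <- out$t > 0
  list(pos = cbind(out$x[keep], out$y[keep]),
       heading = cbind(out$hx[keep], out$hy[keep]),
       speed = out$speed[keep], light = out$light[keep])
}

#' Run a full school simulation through a light-field sequence
#'
#' Initialises the school (positions uniform in the central quarter-area box,
#' headings uniform), seeds the RNG from `config$seed`, and advances
#' `config$steps` steps of `dt` seconds each.  At each step the field frame
#' nearest in time is used (frames are held, not interpolated).  Records the
#' state at `t = 0` and every `record_every`-th step.
#'
#' @param config a [model_config()].
#' @param field a [field_sequence()] generated with `keep_frames = TRUE` and
#'   covering at least `steps * dt` seconds.
#' @return a `data.frame` with columns `t` (s), `id`, `x`, `y` (cm), `hx`,
#'   `hy` (heading), `speed` (cm/s), `light`.
#' @export
run_simulation <- function(config, field) {
  validate_model_config(config)
  if (is.null(field$frames))
    stop("run_simulation needs a field sequence with stored frames")
  dt <- config$social$dt_s
  t_end <- config$steps * dt
  if (max(field$times) + 1 / field$config$frame_rate_hz < t_end)
    stop("field sequence too short for the configured number of steps")
  step_times <- seq_len(config$steps) * dt
  frame_of_step <- vapply(step_times, function(t)
    which.min(abs(field$times - t)), integer(1))
  arena <- c(field$config$arena_width_cm, field$config$arena_height_cm)
  old <- get_seed_state()
  on.exit(restore_seed_state(old))
  set.seed(config$seed)
  st <- init_school(config, arena)
  dims <- c(dim(field$frames)[1:2], dim(field$frames)[3])
  out <- run_school_cpp(st$pos, st$heading, as.numeric(field$frames), dims,
                        frame_of_step, config, arena, grid_spacing(field$config),
                        config$steps, config$record_every)
  traj <- data.frame(t = out$t, id = out$id, x = out$x, y = out$y,
                     hx = out$hx, hy = out$hy,
                     speed = out$speed, light = out$light)
  traj[order(traj$id, traj$t), , drop = FALSE]
}

#' Write / read a trajectory table
#'
#' Plain CSV with header `t,id,x,y[,...]`; times in seconds, positions in cm.
#' Externally produced trajectories in this format (e.g. from video tracking)
#' can be read back and fed to the metric and kinematics functions.
#'
#' @param traj a trajectory `data.frame`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the `data.frame`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.csv(path)
  need <- c("t", "id", "x", "y")
  if (!all(need %in% names(traj)))
    stop("trajectory file must have columns t, id, x, y")
  traj
}
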