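#' Light-field configuration
#'
#' Parameters of the dynamic noisy light field: a circular dark spot with
#' Gaussian decay to white that wanders around the arena at constant speed,
#' superimposed on spatiotemporally correlated greyscale noise, with a white
#' border band.  Defaults reproduce the experimental stimulus: a
#' 183 cm x 102 cm arena projected at 940 x 540 px and 30 Hz, spot length
#' scale 38.1 cm, spot speed 5.7 cm/s, noise level eta = 0.25, and a 50 px
#' white border.
#'
#' @param arena_width_cm,arena_height_cm arena size in cm.
#' @param grid_nx,grid_ny grid resolution in pixels.
#' @param spot_scale_cm Gaussian length scale (sd) of the dark spot, cm.
#' @param spot_speed_cms constant spot speed, cm/s.
#' @param frame_rate_hz frames per second.
#' @param noise_level eta, relative amplitude of the noise component, in
#'   `[0, 1]`.
#' @param border_px width of the white border band, in pixels of this grid.
#' @param duration_s sequence length in seconds.
#' @param seed integer seed; together with the config it fully determines the
#'   generated sequence.
#' @param noise_sigma_cm spatial correlation scale of the noise (Gaussian
#'   smoothing sd, cm).
#' @param noise_tau_s temporal correlation time of the noise (AR(1)
#'   persistence `exp(-1/(frame_rate * tau))` per frame).
#' @param spot_turn_sd sd (radians) of the spot's heading change per frame.
#'   `NULL` (default) uses 0.2 rad per frame at 30 Hz, rescaled by
#'   `sqrt(30 / frame_rate_hz)` so the heading diffusion rate does not depend
#'   on the frame rate.
#' @return a `field_config` list.
#' @export
field_config <- function(arena_width_cm = 183, arena_height_cm = 102,
                         grid_nx = 940, grid_ny = 540,
                         spot_scale_cm = 38.1, spot_speed_cms = 5.7,
                         frame_rate_hz = 30, noise_level = 0.25,
                         border_px = 50, duration_s = 300, seed = 1L,
                         noise_sigma_cm = 10 * 183 / 940,
                         noise_tau_s = 1 / (30 * log(1 / 0.9)),
                         spot_turn_sd = NULL) {
  cfg <- list(arena_width_cm = arena_width_cm, arena_height_cm = arena_height_cm,
              grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              spot_scale_cm = spot_scale_cm, spot_speed_cms = spot_speed_cms,
              frame_rate_hz = frame_rate_hz, noise_level = noise_level,
              border_px = as.integer(border_px), duration_s = duration_s,
              seed = as.integer(seed), noise_sigma_cm = noise_sigma_cm,
              noise_tau_s = noise_tau_s,
              spot_turn_sd = if (is.null(spot_turn_sd))
                0.2 * sqrt(30 / frame_rate_hz) else spot_turn_sd)
  class(cfg) <- "field_config"
  validate_field_config(cfg)
  cfg
}

validate_field_config <- function(cfg) {
  pos <- c("arena_width_cm", "arena_height_cm", "grid_nx", "grid_ny",
           "spot_scale_cm", "spot_speed_cms", "frame_rate_hz", "duration_s",
           "noise_sigma_cm", "noise_tau_s")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("field config: `", f, "` must be a single positive number")
  if (cfg$noise_level < 0 || cfg$noise_level > 1)
    stop("field config: `noise_level` must lie in [0, 1]")
  if (cfg$border_px < 0 || cfg$border_px >= min(cfg$grid_nx, cfg$grid_ny) / 2)
    stop("field config: `border_px` must be < min(grid_nx, grid_ny)/2")
  if (cfg$spot_turn_sd < 0) stop("field config: `spot_turn_sd` must be >= 0")
  invisible(cfg)
}

#' Scale a field configuration to a coarser grid
#'
#' Divides the grid resolution (and the border width with it) by `factor`
#' while keeping all physical parameters, so reduced-resolution sequences can
#' be generated cheaply.  The pixel-to-cm mapping changes accordingly.
#'
#' @param config a [field_config()].
#' @param factor integer down-scaling factor for both grid axes.
#' @return a `field_config`.
#' @export
reduce_field_config <- function(config, factor) {
  config$grid_nx <- as.integer(round(config$grid_nx / factor))
  config$grid_ny <- as.integer(round(config$grid_ny / factor))
  config$border_px <- as.integer(round(config$border_px / factor))
  validate_field_config(config)
  config
}

grid_spacing <- function(config) {
  c(dx = config$arena_width_cm / config$grid_nx,
    dy = config$arena_height_cm / config$grid_ny)
}

# pixel-centre coordinates along each axis
grid_axes <- function(config) {
  d <- grid_spacing(config)
  list(x = (seq_len(config$grid_nx) - 0.5) * d[["dx"]],
       y = (seq_len(config$grid_ny) - 0.5) * d[["dy"]])
}

check_inside <- function(x, config, what = "position") {
  x <- as.numeric(x)
  if (length(x) != 2 || any(!is.finite(x)))
    stop(what, " must be a finite 2-vector")
  if (x[1] < 0 || x[1] > config$arena_width_cm ||
      x[2] < 0 || x[2] > config$arena_height_cm)
    stop(what, " lies outside the arena")
  x
}

#' Dark-spot brightness field
#'
#' Brightness of the moving dark spot alone: a circular dark region with
#' Gaussian decay to white, `L(x) = 1 - exp(-|x - center|^2 / (2 l^2))` with
#' length scale `l = spot_scale_cm`.  Zero (fully dark) at the centre,
#' approaching one (white) far away.
#'
#' @param center spot centre, 2-vector in cm; must lie inside the arena.
#' @param config a [field_config()].
#' @return an `grid_nx` x `grid_ny` matrix of brightness values in `[0, 1]`,
#'   rows indexing x.
#' @export
spot_field <- function(center, config) {
  center <- check_inside(center, config, "spot center")
  ax <- grid_axes(config)
  r2 <- outer((ax$x - center[1])^2, (ax$y - center[2])^2, `+`)
  1 - exp(-r2 / (2 * config$spot_scale_cm^2))
}

reflect_interval <- function(x, lo, hi) {
  # mirror reflection into [lo, hi]; also reports the net sign flip
  sign <- 1
  for (k in 1:8) {
    if (x < lo) { x <- 2 * lo - x; sign <- -sign }
    else if (x > hi) { x <- 2 * hi - x; sign <- -sign }
    else break
  }
  c(x, sign)
}

#' Advance the dark spot by one frame
#'
#' Moves the spot centre by `spot_speed / frame_rate` along its heading, after
#' perturbing the heading by a Gaussian turn (sd `spot_turn_sd`), and reflects
#' off the arena walls so the centre stays inside.  Consumes random numbers
#' from R's global RNG.
#'
#' @param center current centre (cm); must be inside the arena.
#' @param heading current unit heading vector.
#' @param config a [field_config()].
#' @return list with `center` and `heading`.
#' @export
step_spot <- function(center, heading, config) {
  center <- check_inside(center, config, "spot center")
  if (config$spot_turn_sd > 0) {
    a <- stats::rnorm(1, 0, config$spot_turn_sd)
    heading <- rotate_vec(heading, a)
  }
  step <- config$spot_speed_cms / config$frame_rate_hz
  cand <- center + step * heading
  rx <- reflect_interval(cand[1], 0, config$arena_width_cm)
  ry <- reflect_interval(cand[2], 0, config$arena_height_cm)
  list(center = c(rx[1], ry[1]),
       heading = c(heading[1] * rx[2], heading[2] * ry[2]))
}

rotate_vec <- function(v, angle) {
  c(cos(angle) * v[1] - sin(angle) * v[2],
    sin(angle) * v[1] + cos(angle) * v[2])
}

# Gaussian smoothing matrices for the noise synthesis, one per axis.
# Rows are renormalised so smoothing preserves a flat field exactly.
noise_smoothers <- function(config) {
  d <- grid_spacing(config)
  make <- function(n, sigma_px) {
    if (sigma_px <= 0) return(diag(n))
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma_px^2))
    K[K < 1e-8] <- 0
    K / rowSums(K)
  }
  list(Sx = make(config$grid_nx, config$noise_sigma_cm / d[["dx"]]),
       Sy = make(config$grid_ny, config$noise_sigma_cm / d[["dy"]]))
}

# one smoothed, standardised white-noise innovation (unit sd, zero mean)
noise_innovation <- function(config, sm) {
  W <- matrix(stats::rnorm(config$grid_nx * config$grid_ny),
              config$grid_nx, config$grid_ny)
  G <- sm$Sx %*% W %*% t(sm$Sy)
  (G - mean(G)) / stats::sd(G)
}

noise_persistence <- function(config) {
  exp(-1 / (config$frame_rate_hz * config$noise_tau_s))
}

# scale a unit-sd field to the contract range [-0.5, 0.5]
noise_scale <- function(F) {
  pmin(pmax(0.25 * F, -0.5), 0.5)
}

#' Noise field at a given frame
#'
#' The background noise component of the light field: spatially low-pass
#' filtered white noise (Gaussian kernel, scale `noise_sigma_cm`) evolved in
#' time as a first-order autoregressive process (correlation time
#' `noise_tau_s`), standardised to zero mean and scaled into `[-0.5, 0.5]`.
#' Deterministic given `(config$seed, t)`: the recursion is replayed from the
#' first frame, so the cost is proportional to `t`.  [field_sequence()]
#' generates whole sequences without the replay overhead.
#'
#' @param t frame index (1-based).
#' @param config a [field_config()].
#' @return an `grid_nx` x `grid_ny` matrix with values in `[-0.5, 0.5]`.
#' @export
noise_field <- function(t, config) {
  t <- as.integer(t)
  stopifnot(t >= 1)
  sm <- noise_smoothers(config)
  rho <- noise_persistence(config)
  withr_seed <- get_seed_state()
  on.exit(restore_seed_state(withr_seed))
  set.seed(config$seed)
  init_spot_state(config)          # keep RNG stream aligned with field_sequence
  F <- NULL
  for (k in seq_len(t)) {
    if (k > 1) spot_turn_draw(config)
    G <- noise_innovation(config, sm)
    F <- if (k == 1) G else rho * F + sqrt(1 - rho^2) * G
  }
  noise_scale(F)
}

# RNG draw order shared by noise_field and field_sequence:
# frame 1: spot init (3 draws), innovation; frame k>1: spot turn, innovation.
init_spot_state <- function(config) {
  center <- c(stats::runif(1, 0, config$arena_width_cm),
              stats::runif(1, 0, config$arena_height_cm))
  ang <- stats::runif(1, 0, 2 * pi)
  list(center = center, heading = c(cos(ang), sin(ang)))
}

spot_turn_draw <- function(config) {
  if (config$spot_turn_sd > 0) stats::rnorm(1, 0, config$spot_turn_sd)
  invisible(NULL)
}

get_seed_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}

restore_seed_state <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, globalenv())
  invisible(NULL)
}

#' Compose one light-field frame
#'
#' `L = clip(spot + eta * noise, 0, 1)`, then the border band of `border_px`
#' pixels is forced to exactly 1 (white), mirroring the white frame added to
#' the projected field to keep fish away from the tank walls.
#'
#' @param spot spot brightness grid from [spot_field()].
#' @param noise noise grid from [noise_field()] (same dimensions).
#' @param config a [field_config()].
#' @param time_s timestamp attached to the frame.
#' @param spot_center spot centre attached to the frame.
#' @return a `field_frame`: list with `values`, `time_s`, `spot_center`,
#'   `arena` (width, height in cm).
#' @export
compose_frame <- function(spot, noise, config, time_s = 0,
                          spot_center = c(NA_real_, NA_real_)) {
  if (!all(dim(spot) == dim(noise)))
    stop("spot and noise grids have different dimensions")
  if (!all(dim(spot) == c(config$grid_nx, config$grid_ny)))
    stop("grids do not match the configured resolution")
  L <- pmin(pmax(spot + config$noise_level * noise, 0), 1)
  b <- config$border_px
  if (b > 0) {
    nx <- config$grid_nx; ny <- config$grid_ny
    L[c(seq_len(b), nx - seq_len(b) + 1), ] <- 1
    L[, c(seq_len(b), ny - seq_len(b) + 1)] <- 1
  }
  structure(list(values = L, time_s = time_s, spot_center = spot_center,
                 arena = c(config$arena_width_cm, config$arena_height_cm)),
            class = "field_frame")
}

frame_spacing <- function(frame) {
  c(dx = frame$arena[1] / nrow(frame$values),
    dy = frame$arena[2] / ncol(frame$values))
}

#' Sample the light level at a continuous position
#'
#' Bilinear interpolation of the frame grid at an arena position (pixel
#' centres at `(i - 0.5) * dx`); positions outside the pixel-centre hull are
#' clamped to the nearest edge value.
#'
#' @param frame a `field_frame` (or any list with `values` and `arena`).
#' @param x position(s): 2-vector or n x 2 matrix, cm.
#' @return light level(s) in `[0, 1]`.
#' @export
sample_light <- function(frame, x) {
  xy <- as_xy_matrix(x)
  check_in_arena(xy, frame$arena)
  d <- frame_spacing(frame)
  cpp_bilinear(frame$values, xy, d[["dx"]], d[["dy"]])
}

#' Spatial gradient of the light field at a continuous position
#'
#' Central finite differences on the grid (one-sided on the outermost pixel
#' ring), bilinearly interpolated at `x`; units 1/cm.
#'
#' @inheritParams sample_light
#' @return gradient(s): 2-vector or n x 2 matrix (d L/dx, d L/dy) in 1/cm.
#' @export
field_gradient <- function(frame, x) {
  xy <- as_xy_matrix(x)
  check_in_arena(xy, frame$arena)
  d <- frame_spacing(frame)
  g <- cpp_gradient(frame$values, xy, d[["dx"]], d[["dy"]])
  if (is.null(dim(x)) && length(x) == 2) drop(g) else g
}

as_xy_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 2) stop("position must be a 2-vector or an n x 2 matrix")
    matrix(as.numeric(x), 1, 2)
  } else {
    storage.mode(x) <- "double"
    if (ncol(x) != 2) stop("position matrix must have 2 columns")
    x
  }
}

check_in_arena <- function(xy, arena) {
  if (any(xy[, 1] < 0 | xy[, 1] > arena[1] |
          xy[, 2] < 0 | xy[, 2] > arena[2]))
    stop("position lies outside the arena")
  invisible(xy)
}

#' Generate a dynamic light-field sequence
#'
#' Runs the spot random walk and the autoregressive noise process for
#' `duration_s * frame_rate_hz` frames and composes each frame.  Fully
#' determined by `(config, config$seed)`.
#'
#' With `keep_frames = FALSE` the per-frame grids are discarded as the
#' sequence streams (only the running temporal average, the spot track and
#' the light level at the spot centre are kept), which makes long
#' full-resolution sequences tractable in memory.
#'
#' @param config a [field_config()].
#' @param keep_frames keep the full frame stack (`TRUE`) or only summaries.
#' @return a `field_sequence`: list with `frames` (nx x ny x nt array or
#'   `NULL`), `times` (s), `track` (nt x 2 spot centres, cm), `track_light`
#'   (light level at the spot centre per frame), `temporal_average`
#'   (nx x ny grid), and `config`.
#' @export
field_sequence <- function(config, keep_frames = TRUE) {
  validate_field_config(config)
  nt <- as.integer(round(config$duration_s * config$frame_rate_hz))
  nx <- config$grid_nx; ny <- config$grid_ny
  sm <- noise_smoothers(config)
  rho <- noise_persistence(config)
  old <- get_seed_state()
  on.exit(restore_seed_state(old))
  set.seed(config$seed)
  spot <- init_spot_state(config)
  frames <- if (keep_frames) array(NA_real_, c(nx, ny, nt)) else NULL
  track <- matrix(NA_real_, nt, 2)
  track_light <- numeric(nt)
  avg <- matrix(0, nx, ny)
  times <- (seq_len(nt) - 1) / config$frame_rate_hz
  Fn <- NULL
  for (k in seq_len(nt)) {
    if (k > 1) {
      st <- step_spot(spot$center, spot$heading, config)
      spot$center <- st$center; spot$heading <- st$heading
    }
    G <- noise_innovation(config, sm)
    Fn <- if (k == 1) G else rho * Fn + sqrt(1 - rho^2) * G
    fr <- compose_frame(spot_field(spot$center, config), noise_scale(Fn),
                        config, time_s = times[k], spot_center = spot$center)
    if (keep_frames) frames[, , k] <- fr$values
    avg <- avg + fr$values
    track[k, ] <- spot$center
    track_light[k] <- sample_light(fr, spot$center)
  }
  structure(list(frames = frames, times = times, track = track,
                 track_light = track_light, temporal_average = avg / nt,
                 config = config),
            class = "field_sequence")
}

#' Extract one frame of a field sequence
#'
#' @param fs a [field_sequence()] generated with `keep_frames = TRUE`.
#' @param i frame index.
#' @return a `field_frame`.
#' @export
get_frame <- function(fs, i) {
  if (is.null(fs$frames))
    stop("field sequence was generated without frames (keep_frames = FALSE)")
  structure(list(values = fs$frames[, , i], time_s = fs$times[i],
                 spot_center = fs$track[i, ],
                 arena = c(fs$config$arena_width_cm, fs$config$arena_height_cm)),
            class = "field_frame")
}

# frame built from the temporal average grid
average_frame <- function(fs) {
  structure(list(values = fs$temporal_average, time_s = NA_real_,
                 spot_center = c(NA_real_, NA_real_),
                 arena = c(fs$config$arena_width_cm, fs$config$arena_height_cm)),
            class = "field_frame")
}

#' Export a field sequence as greyscale PNG frames
#'
#' Writes each frame as an 8-bit greyscale PNG (brightness scaled 0-255) plus
#' a JSON sidecar with the configuration and spot-centre track.  Requires the
#' `png` package.
#'
#' @param fs a [field_sequence()] with frames.
#' @param dir output directory (created if missing).
#' @return invisibly, the sidecar path.
#' @export
export_frames <- function(fs, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("frame export requires the `png` package")
  if (is.null(fs$frames)) stop("field sequence has no stored frames")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- length(fs$times)
  for (k in seq_len(nt)) {
    # image rows = y from top; grid rows = x
    img <- t(fs$frames[, , k])[ncol(fs$frames[, , k]):1, , drop = FALSE]
    png::writePNG(img, file.path(dir, sprintf("frame_%05d.png", k)))
  }
  sidecar <- file.path(dir, "field.json")
  jsonlite::write_json(
    list(config = unclass(fs$config), times = fs$times,
         track = as.data.frame(fs$track)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
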