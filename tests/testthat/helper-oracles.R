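# Independent reference implementations and small fixture builders used to
# cross-check the package against hand-derivable results.

# a field_frame with explicit values on a given arena
make_frame <- function(values, arena = c(10, 10), time_s = 0,
                       spot_center = c(NA_real_, NA_real_)) {
  structure(list(values = values, time_s = time_s, spot_center = spot_center,
                 arena = arena), class = "field_frame")
}

uniform_frame <- function(level = 0.5, nx = 20, ny = 20, arena = c(10, 10)) {
  make_frame(matrix(level, nx, ny), arena)
}

# linear ramp L = x / W, exact for central differences
ramp_frame <- function(nx = 40, ny = 20, arena = c(20, 10)) {
  dx <- arena[1] / nx
  xs <- (seq_len(nx) - 0.5) * dx
  make_frame(matrix(rep(xs / arena[1], ny), nx, ny), arena)
}

# pure-R zonal social direction, written independently of the compiled path
oracle_social_direction <- function(focal_pos, focal_heading, nb_pos, nb_head,
                                    params, bl) {
  rr <- params$r_repulsion_bl * bl
  ro <- params$r_orientation_bl * bl
  ra <- params$r_attraction_bl * bl
  half <- params$perception_deg / 2 * pi / 180
  rep_sum <- c(0, 0); ori_sum <- c(0, 0); att_sum <- c(0, 0)
  n_rep <- n_ori <- n_att <- 0L
  for (j in seq_len(nrow(nb_pos))) {
    sep <- nb_pos[j, ] - focal_pos
    d <- sqrt(sum(sep^2))
    if (d == 0 || d >= ra) next
    u <- sep / d
    ang <- acos(pmin(pmax(sum(u * focal_heading), -1), 1))
    if (ang > half) next
    if (d < rr) { rep_sum <- rep_sum - u; n_rep <- n_rep + 1L }
    else if (d < ro) { ori_sum <- ori_sum + nb_head[j, ]; n_ori <- n_ori + 1L }
    else { att_sum <- att_sum + u; n_att <- n_att + 1L }
  }
  unit <- function(v) { n <- sqrt(sum(v^2)); if (n > 1e-12) v / n else c(0, 0) }
  if (n_rep > 0) return(unit(rep_sum))
  out <- c(0, 0)
  if (n_ori > 0) out <- out + unit(ori_sum)
  if (n_att > 0) out <- out + unit(att_sum)
  unit(out)
}

rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                         sin(a) * v[1] + cos(a) * v[2])

angle_between <- function(u, v) {
  acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
}

# small field configuration for fast sequence generation in tests
test_field_config <- function(seed = 1, duration_s = 5, frame_rate_hz = 8,
                              noise_level = 0.25, grid = c(94, 54)) {
  field_config(grid_nx = grid[1], grid_ny = grid[2], border_px = 5,
               duration_s = duration_s, frame_rate_hz = frame_rate_hz,
               noise_level = noise_level, seed = seed)
}
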