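#' Raw gradient-tracking performance
#'
#' `psi = <<1 - L>_fish>_t`: the local darkness `1 - L` is averaged over all
#' fish within each frame first, then over frames.  Each trajectory time is
#' matched to the nearest field frame.
#'
#' @param traj trajectory `data.frame` with columns `t`, `id`, `x`, `y`.
#' @param field a [field_sequence()] with stored frames.
#' @return psi in `[0, 1]`.
#' @export
raw_performance <- function(traj, field) {
  if (nrow(traj) == 0) stop("empty trajectory")
  if (is.null(field$frames)) stop("field sequence has no stored frames")
  d <- grid_spacing(field$config)
  times <- sort(unique(traj$t))
  per_frame <- vapply(times, function(tt) {
    rows <- traj[traj$t == tt, , drop = FALSE]
    fi <- which.min(abs(field$times - tt))
    L <- cpp_bilinear(field$frames[, , fi], cbind(rows$x, rows$y),
                      d[["dx"]], d[["dy"]])
    mean(1 - L)
  }, numeric(1))
  mean(per_frame)
}

#' Null performance on the temporal-average field
#'
#' The same frame-then-time averaging as [raw_performance()], but with the
#' light level sampled from the temporal average of the field: the darkness
#' the same trajectories would have experienced had the field been static at
#' its time average.
#'
#' @inheritParams raw_performance
#' @return psi_null in `[0, 1]`.
#' @export
null_performance <- function(traj, field) {
  if (nrow(traj) == 0) stop("empty trajectory")
  avg <- average_frame(field)
  times <- sort(unique(traj$t))
  per_frame <- vapply(times, function(tt) {
    rows <- traj[traj$t == tt, , drop = FALSE]
    mean(1 - sample_light(avg, cbind(rows$x, rows$y)))
  }, numeric(1))
  mean(per_frame)
}

#' Normalised gradient-tracking performance
#'
#' `Psi = psi / psi_null`.  `Psi > 1` means the group tracked the moving dark
#' region better than chance placement on the time-averaged field; on a
#' static field `Psi = 1` for any trajectory.
#'
#' @param psi raw performance.
#' @param psi_null null performance (> 0).
#' @return Psi.
#' @export
tracking_performance <- function(psi, psi_null) {
  if (psi_null <= 0) stop("psi_null must be positive")
  psi / psi_null
}

#' Performance of a trajectory and field pair
#'
#' Convenience wrapper returning psi, psi_null and Psi together.
#'
#' @inheritParams raw_performance
#' @return list with `psi`, `psi_null`, `Psi`.
#' @export
performance <- function(traj, field) {
  psi <- raw_performance(traj, field)
  psi_null <- null_performance(traj, field)
  list(psi = psi, psi_null = psi_null,
       Psi = tracking_performance(psi, psi_null))
}

#' Maximum achievable performance of a field sequence
#'
#' The performance of the ideal single-point trajectory that sits at the
#' dark-spot centre in every frame: it maximises darkness while its null
#' performance is evaluated on the temporal-average field, giving the upper
#' bound `Psi_max` on group performance.  Works on sequences generated with
#' `keep_frames = FALSE`, since the light level along the spot track is
#' recorded during generation.
#'
#' @param field a [field_sequence()].
#' @return list with `psi`, `psi_null`, `Psi` for the spot-centre tracker.
#' @export
max_performance <- function(field) {
  if (is.null(field$track) || is.null(field$track_light))
    stop("field sequence carries no spot-centre track")
  psi <- mean(1 - field$track_light)
  psi_null <- mean(1 - sample_light(average_frame(field), field$track))
  list(psi = psi, psi_null = psi_null,
       Psi = tracking_performance(psi, psi_null))
}

#' Mean nearest-neighbour distance
#'
#' For one frame of positions: the mean over agents of the distance to each
#' agent's nearest other agent.  For a trajectory: that frame value averaged
#' over all recorded frames.
#'
#' @param x either an N x 2 position matrix (one frame) or a trajectory
#'   `data.frame` with `t`, `id`, `x`, `y`.
#' @return d_nn in the units of the positions (cm).
#' @export
nearest_neighbour_distance <- function(x) {
  if (is.data.frame(x)) {
    times <- unique(x$t)
    return(mean(vapply(times, function(tt) {
      rows <- x[x$t == tt, , drop = FALSE]
      nn_frame(cbind(rows$x, rows$y))
    }, numeric(1))))
  }
  nn_frame(as_xy_matrix(x))
}

nn_frame <- function(pos) {
  n <- nrow(pos)
  if (n < 2) stop("nearest-neighbour distance needs at least 2 agents")
  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf
  mean(apply(D, 1, min))
}

#' Group area and number density
#'
#' `A_group` is the convex-hull area of the positions; the number density is
#' `rho = A_group / (N * BL^2)`.  Collinear or coincident configurations get
#' zero area (with a warning).
#'
#' @param positions N x 2 matrix, cm.
#' @param body_length_cm body length, cm.
#' @return list with `A_group` (cm^2), `d_nn` (cm), `rho`, `n_agents`.
#' @export
group_area_density <- function(positions, body_length_cm = 3.4) {
  pos <- as_xy_matrix(positions)
  n <- nrow(pos)
  if (n < 3) stop("group area needs at least 3 agents")
  hull <- grDevices::chull(pos)
  hx <- pos[hull, 1]; hy <- pos[hull, 2]
  # shoelace formula over the hull polygon
  A <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (A == 0) warning("degenerate (collinear) positions: zero group area")
  list(A_group = A, d_nn = nn_frame(pos), rho = A / (n * body_length_cm^2),
       n_agents = n)
}

#' Summarise a sweep table
#'
#' Aggregates per-cell results over replicates: mean and standard error of
#' `Psi` and `d_nn` for every `(w, N, eta)` combination.
#'
#' @param cells tidy `data.frame` with columns `w`, `N`, `eta`, `replicate`,
#'   `Psi`, `d_nn` (one row per run), as returned by [run_sweep()].
#' @return a `data.frame` with columns `w`, `N`, `eta`, `Psi_mean`, `Psi_se`,
#'   `d_nn_mean`, `d_nn_se`, `n_rep`.
#' @export
summarise_sweep <- function(cells) {
  need <- c("w", "N", "eta", "Psi", "d_nn")
  if (!all(need %in% names(cells)))
    stop("sweep table needs columns ", paste(need, collapse = ", "))
  key <- interaction(cells$w, cells$N, cells$eta, drop = TRUE)
  agg <- lapply(split(cells, key), function(g) {
    data.frame(w = g$w[1], N = g$N[1], eta = g$eta[1],
               Psi_mean = mean(g$Psi),
               Psi_se = stats::sd(g$Psi) / sqrt(nrow(g)),
               d_nn_mean = mean(g$d_nn),
               d_nn_se = stats::sd(g$d_nn) / sqrt(nrow(g)),
               n_rep = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$eta, out$N, out$w), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sweep_slice <- function(summary, N, eta) {
  s <- summary[summary$N == N & summary$eta == eta, , drop = FALSE]
  if (nrow(s) < 2) stop("sweep slice has fewer than two weights")
  s[order(s$w), , drop = FALSE]
}

#' Maximum performance gain over the weight grid
#'
#' `delta_Psi = max_w mean Psi(w) - mean Psi(w -> 0)`, where the smallest
#' grid weight stands in for `w = 0` (the log grid excludes zero; the two
#' agree within noise because tiny weights are socially dominated).
#'
#' @param summary output of [summarise_sweep()].
#' @param N,eta the sweep slice to evaluate.
#' @return delta_Psi.
#' @export
performance_gain <- function(summary, N, eta) {
  s <- sweep_slice(summary, N, eta)
  max(s$Psi_mean) - s$Psi_mean[1]
}

#' Weight at half-maximum performance
#'
#' The weight `w0` at which the replicate-mean Psi(w) first crosses
#' `Psi(w -> 0) + delta_Psi / 2` upward, found by log-linear interpolation in
#' `w` between grid points.
#'
#' @inheritParams performance_gain
#' @return w0.
#' @export
half_max_weight <- function(summary, N, eta) {
  s <- sweep_slice(summary, N, eta)
  base <- s$Psi_mean[1]
  dPsi <- max(s$Psi_mean) - base
  if (dPsi <= 0) stop("flat performance curve: no half-maximum crossing")
  target <- base + dPsi / 2
  for (k in seq_len(nrow(s) - 1)) {
    y0 <- s$Psi_mean[k]; y1 <- s$Psi_mean[k + 1]
    if (y0 < target && y1 >= target) {
      f <- (target - y0) / (y1 - y0)
      return(10^(log10(s$w[k]) + f * (log10(s$w[k + 1]) - log10(s$w[k]))))
    }
    if (y0 == target) return(s$w[k])
  }
  if (s$Psi_mean[1] >= target) return(s$w[1])
  stop("no upward crossing of the half-maximum level")
}

#' Cohesion-optimal weight across group sizes
#'
#' The grid weight minimising the summed squared excess of the mean
#' nearest-neighbour distance above its per-group-size minimum:
#' `argmin_w sum_N (d_nn(w, N) - min_w' d_nn(w', N))^2`.  This selects the
#' weight that keeps all group sizes simultaneously close to their tightest
#' cohesion.
#'
#' @param summary output of [summarise_sweep()].
#' @param sizes group sizes to include.
#' @param eta noise level of the slice.
#' @return list with `w_min` (the selected weight) and `objective` (a
#'   `data.frame` of the summed squared excess per grid weight).
#' @export
select_w_min <- function(summary, sizes = c(16, 32, 64, 128), eta = 0.25) {
  slices <- lapply(sizes, function(n) sweep_slice(summary, n, eta))
  grid <- slices[[1]]$w
  for (s in slices)
    if (!isTRUE(all.equal(s$w, grid)))
      stop("group sizes do not share a common weight grid")
  obj <- rep(0, length(grid))
  for (s in slices)
    obj <- obj + (s$d_nn_mean - min(s$d_nn_mean))^2
  list(w_min = grid[which.min(obj)],
       objective = data.frame(w = grid, sum_sq_excess = obj))
}
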