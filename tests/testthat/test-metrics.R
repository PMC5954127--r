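# a tiny static "sequence" whose every frame equals `values`
static_sequence <- function(values, arena = c(10, 10), nt = 4) {
  cfg <- field_config(arena_width_cm = arena[1], arena_height_cm = arena[2],
                      grid_nx = nrow(values), grid_ny = ncol(values),
                      border_px = 0, frame_rate_hz = 2, duration_s = nt / 2)
  structure(list(frames = array(rep(values, nt),
                                c(nrow(values), ncol(values), nt)),
                 times = (seq_len(nt) - 1) / 2,
                 track = NULL, track_light = NULL,
                 temporal_average = values, config = cfg),
            class = "field_sequence")
}

test_that("raw performance averages darkness over fish then time", {
  # one frame, two fish at L = 0.2 and 0.6 -> psi = 0.6
  vals <- matrix(0.2, 10, 10)
  vals[8, ] <- 0.6
  fs <- static_sequence(vals, nt = 1)
  d <- grid_spacing(fs$config)
  traj <- data.frame(t = c(0, 0), id = 1:2,
                     x = c((3 - 0.5) * d[["dx"]], (8 - 0.5) * d[["dx"]]),
                     y = (5 - 0.5) * d[["dy"]])  # pixel centres
  expect_equal(raw_performance(traj, fs), (0.8 + 0.4) / 2)
  # extremes
  fs0 <- static_sequence(matrix(0, 10, 10), nt = 2)
  traj2 <- data.frame(t = c(0, 0.5), id = 1, x = 5, y = 5)
  expect_equal(raw_performance(traj2, fs0), 1)
  fs1 <- static_sequence(matrix(1, 10, 10), nt = 2)
  expect_equal(raw_performance(traj2, fs1), 0)
  expect_error(raw_performance(traj2[0, ], fs1), "empty")
})

test_that("performance is invariant to relabelling and reordering", {
  fcfg <- test_field_config(seed = 31, duration_s = 4)
  fs <- field_sequence(fcfg)
  cfg <- model_config(n_agents = 6, w = 1, steps = 24, record_every = 4,
                      seed = 13)
  traj <- run_simulation(cfg, fs)
  base <- raw_performance(traj, fs)
  shuf <- traj[sample(nrow(traj)), ]
  shuf$id <- match(shuf$id, c(3, 1, 6, 2, 5, 4))
  expect_equal(raw_performance(shuf, fs), base)
})

test_that("on a static field Psi is exactly 1", {
  vals <- matrix(stats::runif(200), 20, 10)
  fs <- static_sequence(vals, nt = 5)
  set.seed(2)
  traj <- data.frame(t = rep(fs$times, each = 3), id = rep(1:3, 5),
                     x = stats::runif(15, 0, 10), y = stats::runif(15, 0, 10))
  p <- performance(traj, fs)
  expect_equal(p$psi, p$psi_null)
  expect_equal(p$Psi, 1)
})

test_that("null performance samples the temporal average", {
  vals <- matrix(0.4, 10, 10)
  fs <- static_sequence(vals, nt = 3)
  traj <- data.frame(t = fs$times, id = 1, x = 5, y = 5)
  expect_equal(null_performance(traj, fs), 0.6)
  expect_equal(tracking_performance(0.6, 0.3), 2)
  expect_error(tracking_performance(0.5, 0), "positive")
})

test_that("max performance tracks the spot centre and bounds school performance", {
  # static centred spot: Psi_max = 1
  cfg <- field_config(grid_nx = 94, grid_ny = 54, border_px = 0,
                      noise_level = 0, spot_speed_cms = 1e-9,
                      spot_turn_sd = 0, frame_rate_hz = 4, duration_s = 2,
                      seed = 6)
  fs <- field_sequence(cfg)
  expect_equal(max_performance(fs)$Psi, 1, tolerance = 1e-9)
  # on a dynamic field the spot tracker is genuinely better than chance
  fcfg <- test_field_config(seed = 32, duration_s = 60)
  fsd <- field_sequence(fcfg, keep_frames = FALSE)
  expect_gt(max_performance(fsd)$Psi, 1)
})

test_that("nearest neighbour distance enumerates pairs", {
  expect_equal(nearest_neighbour_distance(rbind(c(0, 0), c(4, 0))), 4)
  # collinear agents at 0, d, 2d -> mean(d, d, d) = d
  expect_equal(nearest_neighbour_distance(rbind(c(0, 0), c(3, 0), c(6, 0))), 3)
  # homogeneity under scaling
  set.seed(4)
  pos <- matrix(stats::runif(20, 0, 10), 10, 2)
  expect_equal(nearest_neighbour_distance(pos * 2.5),
               2.5 * nearest_neighbour_distance(pos))
  # trajectory form: mean over frames
  traj <- data.frame(t = c(0, 0, 1, 1), id = c(1, 2, 1, 2),
                     x = c(0, 1, 0, 3), y = 0)
  expect_equal(nearest_neighbour_distance(traj), 2)
  expect_error(nearest_neighbour_distance(matrix(0, 1, 2)), "at least 2")
})

test_that("group area and density use the convex hull", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  g <- group_area_density(sq, body_length_cm = 1)
  expect_equal(g$A_group, 1)
  expect_equal(g$rho, 1 / 4)
  # interior points do not change the hull
  g2 <- group_area_density(rbind(sq, c(0.5, 0.5)), body_length_cm = 1)
  expect_equal(g2$A_group, 1)
  # doubling BL quarters rho
  expect_equal(group_area_density(sq, body_length_cm = 2)$rho, g$rho / 4)
  expect_warning(group_area_density(rbind(c(0, 0), c(1, 1), c(2, 2))),
                 "collinear")
})

# hand-built sweep table: Psi rises sigmoidally, d_nn is U-shaped
toy_sweep <- function() {
  w <- 10^seq(-2, 3, length.out = 6)
  rows <- list()
  for (n in c(16, 32)) {
    psi <- c(1.0, 1.0, 1.2, 1.8, 1.7, 1.7)
    dnn <- c(5, 4, 3, 2 + (n == 32), 4, 8)
    for (r in 1:2)
      rows[[length(rows) + 1]] <-
        data.frame(w = w, N = n, eta = 0.25, replicate = r,
                   Psi = psi, d_nn = dnn)
  }
  do.call(rbind, rows)
}

test_that("performance gain and half-max weight follow hand calculations", {
  s <- summarise_sweep(toy_sweep())
  expect_equal(performance_gain(s, 16, 0.25), 0.8)
  # half max level = 1.0 + 0.4 = 1.4, crossed between grid points 3 and 4
  w <- 10^seq(-2, 3, length.out = 6)
  f <- (1.4 - 1.2) / (1.8 - 1.2)
  expect_equal(half_max_weight(s, 16, 0.25),
               10^(log10(w[3]) + f * (log10(w[4]) - log10(w[3]))))
  flat <- toy_sweep()
  flat$Psi <- 1
  expect_error(half_max_weight(summarise_sweep(flat), 16, 0.25), "flat")
})

test_that("half-max weight recovers the midpoint of a logistic in log w", {
  w <- 10^seq(-2, 3, length.out = 32)
  mid <- 10^0.7
  psi <- 1 + 1 / (1 + exp(-(log10(w) - log10(mid)) / 0.3))
  tab <- data.frame(w = rep(w, 2), N = 32, eta = 0.25,
                    replicate = rep(1:2, each = 32), Psi = rep(psi, 2),
                    d_nn = 1)
  got <- half_max_weight(summarise_sweep(tab), 32, 0.25)
  spacing <- 5 / 31
  expect_lt(abs(log10(got) - log10(mid)), spacing)
})

test_that("cohesion-optimal weight minimises the summed squared excess", {
  s <- summarise_sweep(toy_sweep())
  # N = 16 minimum at grid point 4, N = 32 at the same w -> shared minimiser
  w <- 10^seq(-2, 3, length.out = 6)
  expect_equal(select_w_min(s, sizes = c(16, 32))$w_min, w[4])
  # invariance: adding a constant to one size's d_nn leaves the choice alone
  shifted <- toy_sweep()
  shifted$d_nn[shifted$N == 32] <- shifted$d_nn[shifted$N == 32] + 2.3
  expect_equal(select_w_min(summarise_sweep(shifted), sizes = c(16, 32))$w_min,
               w[4])
  # two sizes with minima at adjacent grid points: enumerate the objective
  tab <- toy_sweep()
  tab$d_nn[tab$N == 32] <- rep(c(5, 4, 2, 3, 4, 8), 2)  # minimum at point 3
  s2 <- summarise_sweep(tab)
  dn16 <- c(5, 4, 3, 2, 4, 8); dn32 <- c(5, 4, 2, 3, 4, 8)
  obj <- (dn16 - 2)^2 + (dn32 - 2)^2
  expect_equal(select_w_min(s2, sizes = c(16, 32))$w_min, w[which.min(obj)])
  expect_equal(select_w_min(s2, sizes = c(16, 32))$objective$sum_sq_excess, obj)
})
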