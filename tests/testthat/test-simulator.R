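test_that("speed modulation is linear in the light level", {
  expect_equal(speed_from_light(0, 2, 10), 2)
  expect_equal(speed_from_light(1, 2, 10), 10)
  expect_equal(speed_from_light(0.5, 2, 10), 6)
  expect_error(speed_from_light(1.2, 2, 10), "\\[0, 1\\]")
})

test_that("environmental direction descends the gradient with sensing error", {
  # uniform field: inside the dark region the gradient is zero
  expect_equal(environmental_direction(uniform_frame(0.4), c(5, 5)), c(0, 0))
  # ramp brightening toward +x: steepest descent is -x
  fr <- ramp_frame()
  expect_equal(environmental_direction(fr, c(10, 5), sigma_w = 0), c(-1, 0))
  # huge sigma_w: directions become uniform on the circle
  set.seed(5)
  n <- 1e4
  dirs <- t(vapply(seq_len(n), function(i)
    environmental_direction(fr, c(10, 5), sigma_w = 10), numeric(2)))
  resultant <- sqrt(sum(colMeans(dirs)^2))
  expect_lt(resultant, 3 / sqrt(n) * 3)
})

test_that("desired direction weights environmental against social information", {
  expect_equal(desired_direction(c(1, 0), c(0, 1), 0), c(1, 0))
  expect_equal(desired_direction(c(1, 0), c(0, 0), 7), c(1, 0))
  d <- desired_direction(c(1, 0), c(0, 1), 1)
  expect_equal(d / sqrt(sum(d^2)), c(1, 1) / sqrt(2))
})

test_that("a lone agent in uniform bright light swims straight at s_max", {
  cfg <- model_config(n_agents = 1, w = 5, steps = 8, record_every = 1,
                      seed = 2, social = social_params(social_error_sd = 0))
  fs <- list(frames = array(1, c(30, 30, 9)), times = (0:8) * 0.125,
             track = NULL, track_light = NULL,
             temporal_average = matrix(1, 30, 30),
             config = field_config(arena_width_cm = 90, arena_height_cm = 90,
                                   grid_nx = 30, grid_ny = 30, border_px = 0,
                                   frame_rate_hz = 8, duration_s = 9 / 8))
  traj <- run_simulation(cfg, fs)
  s_max <- cfg$s_max_bls * cfg$body_length_cm
  expect_true(all(abs(traj$speed - s_max) < 1e-12))
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_true(all(abs(steps - s_max * 0.125) < 1e-9))
  # straight line: headings never change
  expect_equal(stats::sd(traj$hx), 0, tolerance = 1e-12)
})

test_that("two mutually visible agents in the attraction shell approach", {
  cfg <- model_config(n_agents = 2, w = 0, steps = 10, record_every = 1,
                      seed = 3, social = social_params(social_error_sd = 0))
  fs <- list(frames = array(0.5, c(30, 30, 11)), times = (0:10) * 0.125,
             config = field_config(arena_width_cm = 90, arena_height_cm = 90,
                                   grid_nx = 30, grid_ny = 30, border_px = 0,
                                   frame_rate_hz = 8, duration_s = 11 / 8))
  # place agents facing each other 4 BL apart via a manual stepping loop
  bl <- cfg$body_length_cm
  st <- list(pos = rbind(c(45 - 2 * bl, 45), c(45 + 2 * bl, 45)),
             heading = rbind(c(1, 0), c(-1, 0)))
  fr <- make_frame(matrix(0.5, 30, 30), c(90, 90))
  seps <- numeric(7)
  for (k in 1:7) {
    st <- step_school(st, fr, cfg)
    seps[k] <- sqrt(sum((st$pos[1, ] - st$pos[2, ])^2))
  }
  expect_true(all(diff(c(4 * bl, seps)) < 0))
})

test_that("simulations are seed-deterministic and respect speed bounds", {
  fcfg <- test_field_config(seed = 21, duration_s = 13)
  fs <- field_sequence(fcfg)
  cfg <- model_config(n_agents = 12, w = 3, sigma_w = 0.5, steps = 100,
                      record_every = 10, seed = 77)
  t1 <- run_simulation(cfg, fs)
  t2 <- run_simulation(cfg, fs)
  expect_identical(t1, t2)
  s_min <- cfg$s_min_bls * cfg$body_length_cm
  s_max <- cfg$s_max_bls * cfg$body_length_cm
  expect_true(all(t1$speed >= s_min & t1$speed <= s_max))
  expect_true(all(t1$x >= 0 & t1$x <= fcfg$arena_width_cm))
  expect_true(all(t1$y >= 0 & t1$y <= fcfg$arena_height_cm))
  # record count: steps / record_every + 1 per agent, t strictly increasing
  expect_equal(nrow(t1), 12 * (100 / 10 + 1))
  expect_true(all(tapply(t1$t, t1$id, function(x) all(diff(x) > 0))))
})

test_that("per-step heading changes respect the turn limit plus noise", {
  fcfg <- test_field_config(seed = 22, duration_s = 8)
  fs <- field_sequence(fcfg)
  cfg <- model_config(n_agents = 8, w = 10, sigma_w = 0.2, steps = 40,
                      record_every = 1, seed = 5)
  traj <- run_simulation(cfg, fs)
  max_turn <- 100 * pi / 180 * 0.125
  bound <- max_turn + 5 * (cfg$social$social_error_sd + cfg$sigma_w)
  viol <- 0L
  for (id in unique(traj$id)) {
    g <- traj[traj$id == id, ]
    h <- cbind(g$hx, g$hy)
    for (k in seq_len(nrow(h) - 1)) {
      # wall reflections legitimately flip the heading; skip those steps
      near_wall <- g$x[k + 1] < 2 || g$x[k + 1] > fcfg$arena_width_cm - 2 ||
                   g$y[k + 1] < 2 || g$y[k + 1] > fcfg$arena_height_cm - 2
      if (near_wall) next
      if (angle_between(h[k, ], h[k + 1, ]) > bound) viol <- viol + 1L
    }
  }
  expect_equal(viol, 0L)
})

test_that("w = 0 is bit-identical to disabling the environmental term", {
  fcfg <- test_field_config(seed = 23, duration_s = 8)
  fs <- field_sequence(fcfg)
  base <- model_config(n_agents = 10, w = 0, sigma_w = 2, steps = 48,
                       record_every = 8, seed = 9)
  off <- base
  off$env_enabled <- FALSE
  off$w <- 5  # weight is irrelevant once the term is disabled
  expect_identical(run_simulation(base, fs)[c("t", "id", "x", "y")],
                   run_simulation(off, fs)[c("t", "id", "x", "y")])
})

test_that("a lone gradient-sensing agent climbs into the dark spot", {
  # static noise-free spot field
  cfg <- field_config(grid_nx = 188, grid_ny = 108, border_px = 0,
                      noise_level = 0, frame_rate_hz = 8, duration_s = 40,
                      spot_speed_cms = 1e-9, spot_turn_sd = 0, seed = 1)
  center <- c(130, 60)
  nt <- as.integer(40 * 8)
  sp <- spot_field(center, cfg)
  fs <- list(frames = array(rep(sp, nt), c(188, 108, nt)),
             times = (seq_len(nt) - 1) / 8, config = cfg)
  mcfg <- model_config(n_agents = 1, w = 100, sigma_w = 0, steps = 300,
                       record_every = 50, seed = 4,
                       social = social_params(social_error_sd = 0))
  traj <- run_simulation(mcfg, fs)
  last <- traj[traj$t == max(traj$t), ]
  expect_lt(sqrt((last$x - center[1])^2 + (last$y - center[2])^2),
            cfg$spot_scale_cm)
})

test_that("trajectory tables round-trip through CSV", {
  traj <- data.frame(t = c(0, 0.5, 0, 0.5), id = c(1, 1, 2, 2),
                     x = c(1, 2, 3, 4), y = c(4, 3, 2, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back, traj)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_trajectory(bad), "columns")
})
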