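test_that("configuration validation rejects unphysical inputs", {
  expect_error(simulation_config(D = c(-1, 0.1, 0.2)), "must be >= 0")
  bad <- default_rate_matrix(); bad[1, 2] <- -0.5
  expect_error(simulation_config(rate_matrix = bad), "rates must be >= 0")
  expect_error(simulation_config(initial_occupancy = c(0.5, 0.5, 0.5)),
               "probability vector")
  expect_error(simulation_config(frame_interval = 0), "frame_interval")
  # all-zero rates with several states are valid: no switching
  cfg <- simulation_config(rate_matrix = matrix(0, 3, 3),
                           n_particles = 5, seed = 3)
  paths <- simulate_state_paths(cfg)
  expect_true(all(vapply(paths, function(s) length(unique(s)) == 1,
                         logical(1))))
})

test_that("single-state configurations give constant state paths", {
  cfg <- simulation_config(n_states = 1, D = 0.05,
                           rate_matrix = matrix(0, 1, 1),
                           n_particles = 20, seed = 2)
  paths <- simulate_state_paths(cfg)
  expect_true(all(unlist(paths) == 1L))
  expect_true(all(vapply(paths, length, integer(1)) >= 2))
})

test_that("state-path occupancy converges to the stationary distribution", {
  # symmetric 2-state chain: stationary (0.5, 0.5)
  k2 <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  cfg <- simulation_config(n_states = 2, D = c(0.01, 0.1), rate_matrix = k2,
                           bleach_rate = 0, max_frames = 250,
                           n_particles = 200, seed = 11)
  paths <- simulate_state_paths(cfg)
  frac1 <- vapply(paths, function(s) mean(s == 1L), numeric(1))
  se <- stats::sd(frac1) / sqrt(length(frac1))
  expect_lt(abs(mean(frac1) - 0.5), 3 * se)

  # 3-state chain with the default generator vs its analytic stationary
  cfg3 <- simulation_config(bleach_rate = 0, max_frames = 250,
                            n_particles = 400, seed = 12)
  paths3 <- simulate_state_paths(cfg3)
  expect_gte(sum(lengths(paths3)), 1e5)
  pi_true <- stationary_distribution(default_rate_matrix())
  for (k in 1:3) {
    fk <- vapply(paths3, function(s) mean(s == k), numeric(1))
    se <- stats::sd(fk) / sqrt(length(fk))
    expect_lt(abs(mean(fk) - pi_true[k]), 3 * se)
  }
})

test_that("displacements follow the Brownian + localization-noise model", {
  # D = 0, sigma = 0: all observed steps exactly zero
  cfg0 <- simulation_config(n_states = 1, D = 0,
                            rate_matrix = matrix(0, 1, 1), loc_sigma = 0,
                            n_particles = 10, seed = 4)
  traj0 <- simulate_trajectories(cfg0)
  st0 <- to_steps(traj0, cfg0$frame_interval)
  expect_true(all(unlist(lapply(st0, `[[`, "r")) == 0))

  # single state: mean squared step = 4 D t + 4 sigma^2 within 3 SE
  cfg <- simulation_config(n_states = 1, D = 0.05,
                           rate_matrix = matrix(0, 1, 1), loc_sigma = 0.02,
                           bleach_rate = 0, max_frames = 201,
                           n_particles = 500, seed = 5)
  traj <- simulate_trajectories(cfg)
  r2 <- unlist(lapply(to_steps(traj, cfg$frame_interval), `[[`, "r"))^2
  expect_gte(length(r2), 1e5)
  expected <- 4 * 0.05 * cfg$frame_interval + 4 * 0.02^2
  se <- stats::sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - expected), 3 * se)

  # immobile state with loc_sigma = 0.03/sqrt(pi): mean step ~ 0.03 um
  sig <- 0.03 / sqrt(pi)
  cfgi <- simulation_config(n_states = 1, D = 0,
                            rate_matrix = matrix(0, 1, 1), loc_sigma = sig,
                            bleach_rate = 0, max_frames = 101,
                            n_particles = 200, seed = 6)
  ri <- unlist(lapply(to_steps(simulate_trajectories(cfgi),
                               cfgi$frame_interval), `[[`, "r"))
  se <- stats::sd(ri) / sqrt(length(ri))
  expect_lt(abs(mean(ri) - 0.03), 3 * se)
})

test_that("identical seeds reproduce trajectories bit-identically", {
  cfg <- simulation_config(n_particles = 30, seed = 99)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
  cfg2 <- simulation_config(n_particles = 30, seed = 100)
  expect_false(identical(simulate_trajectories(cfg),
                         simulate_trajectories(cfg2)))
})

test_that("movie rendering places photons where particles are", {
  # zero particles: pixels distributed around offset
  empty <- data.frame(particle_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0))
  im <- imaging_params(photons = 0, background = 0, gain = 20, offset = 100,
                       read_noise = 3)
  mv <- render_movie(empty, im, field_size = 3.2, n_frames = 5, seed = 1)
  px <- unlist(mv$frames)
  expect_lt(abs(mean(px) - 100), 1)
  expect_lt(stats::sd(px), 3 * 1.5)

  # one bright static particle, no read noise, gain 1, offset 0:
  # the argmax pixel is the particle's pixel
  traj <- data.frame(particle_id = 1, frame = 0, x_um = 0.72, y_um = 1.20)
  im2 <- imaging_params(photons = 1e5, background = 0, gain = 1, offset = 0,
                        read_noise = 0)
  mv2 <- render_movie(traj, im2, field_size = 3.2, seed = 2)
  amax <- which(mv2$frames[[1]] == max(mv2$frames[[1]]), arr.ind = TRUE)
  expect_equal(unname(amax[1, "col"]), ceiling(0.72 / 0.160))
  expect_equal(unname(amax[1, "row"]), ceiling(1.20 / 0.160))

  # rendering is deterministic under a fixed seed
  expect_identical(render_movie(traj, im2, field_size = 3.2, seed = 2),
                   mv2)
})

test_that("trajectory CSV round-trips", {
  cfg <- simulation_config(n_particles = 5, seed = 8)
  traj <- simulate_trajectories(cfg)
  path <- tempfile(fileext = ".csv")
  write_trajectories(traj, path)
  back <- read_trajectories(path)
  expect_equal(back$x_um, traj$x_um, tolerance = 1e-12)
  expect_equal(back$state_true, traj$state_true)
  expect_error(read_trajectories({
    p <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p, row.names = FALSE)
    p
  }), "must have columns")
})
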