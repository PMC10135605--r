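
# Background stack generator: per-pixel photon flux rises across columns
# from 0 (so the darkest pixels carry offset and read noise only).
make_background_stack <- function(nf = 50, ny = 24, nx = 24, gain = 20,
                                  offset = 100, read_noise = 5,
                                  max_flux = 30, seed = 1) {
  set.seed(seed)
  flux <- matrix(rep(seq(0, max_flux, length.out = nx), each = ny), ny, nx)
  arr <- array(0, c(ny, nx, nf))
  for (f in seq_len(nf)) {
    counts <- matrix(stats::rpois(ny * nx, flux), ny, nx)
    arr[, , f] <- offset + gain * counts +
      matrix(stats::rnorm(ny * nx, 0, read_noise), ny, nx)
  }
  arr
}

test_that("EMCCD calibration recovers gain, offset and read noise", {
  stack <- make_background_stack(nf = 50, gain = 20, offset = 100,
                                 read_noise = 5)
  cal <- calibrate_emccd(stack)
  expect_lt(abs(cal$gain - 20) / 20, 0.10)
  expect_lt(abs(cal$offset - 100), 3)
  expect_lt(abs(cal$read_noise - 5), 2)
  # a constant (noise-free) stack leaves the gain indeterminate
  expect_error(calibrate_emccd(array(100, c(8, 8, 12))), "indeterminate")
  expect_error(calibrate_emccd(array(100, c(8, 8, 5))), ">= 10")
})

test_that("gain estimate is invariant to doubling the illumination", {
  g1 <- calibrate_emccd(make_background_stack(max_flux = 20, seed = 2))$gain
  g2 <- calibrate_emccd(make_background_stack(max_flux = 40, seed = 3))$gain
  expect_lt(abs(g1 - g2) / g1, 0.1)
})

test_that("spot detection finds isolated emitters and merges close ones", {
  blank <- matrix(0, 32, 32)
  expect_equal(nrow(detect_spots(blank, 5, 10)), 0)

  two <- sptstates:::render_spots_photons(32, 32, c(10.5, 20.5), c(16.5, 16.5),
                                          sigma = 1.2, photons = 500)
  det <- detect_spots(two, min_separation = 5, threshold = 10)
  expect_equal(nrow(det), 2)
  det <- det[order(det$x_px), ]
  expect_lt(max(abs(det$x_px - c(10.5, 20.5))), 1)
  expect_lt(max(abs(det$y_px - 16.5)), 1)

  close <- sptstates:::render_spots_photons(32, 32, c(15.5, 16.5), c(16.5, 16.5),
                                            sigma = 1.2, photons = 500)
  expect_equal(nrow(detect_spots(close, min_separation = 5, threshold = 10)),
               1)
})

test_that("PSF fitting is exact on noiseless crops and unbiased under noise", {
  true_par <- c(x0 = 4.5, y0 = 4.5, sigma = 1.2, N = 800, bg = 3)
  crop <- sptstates:::psf_model_image(true_par, 9, 9)
  fit <- fit_psf(crop)
  expect_true(fit$converged)
  expect_lt(abs(fit$x0 - 4.5), 1e-6)
  expect_lt(abs(fit$y0 - 4.5), 1e-6)

  off_par <- c(x0 = 4.8, y0 = 4.1, sigma = 1.2, N = 800, bg = 3)
  fit2 <- fit_psf(sptstates:::psf_model_image(off_par, 9, 9))
  expect_lt(abs(fit2$x0 - 4.8), 1e-3)
  expect_lt(abs(fit2$y0 - 4.1), 1e-3)

  # photon count recovered without bias over Poisson realizations
  set.seed(21)
  lambda <- sptstates:::psf_model_image(true_par, 9, 9)
  phot <- replicate(100, {
    noisy <- matrix(stats::rpois(81, lambda), 9, 9)
    fit_psf(noisy)$photons
  })
  se <- stats::sd(phot) / sqrt(length(phot))
  expect_lt(abs(mean(phot) - 800), 3 * se)
})

test_that("fitted photon count absorbs a constant background offset", {
  true_par <- c(x0 = 4.5, y0 = 4.5, sigma = 1.2, N = 600, bg = 2)
  crop <- sptstates:::psf_model_image(true_par, 9, 9)
  f1 <- fit_psf(crop)
  f2 <- fit_psf(crop + 7)
  expect_lt(abs(f1$photons - f2$photons) / f1$photons, 1e-6)
  expect_lt(abs(f2$background - f1$background - 7), 1e-6)
})

test_that("localization error scales as 1/sqrt(photons)", {
  emccd <- emccd_model(offset = 100, gain = 20, read_noise = 1)
  fit_at <- function(N) {
    structure(list(x0 = 4.5, y0 = 4.5, sigma = 1.2, photons = N,
                   background = 1, converged = TRUE), class = "spt_psf_fit")
  }
  errs <- vapply(c(250, 1000, 4000), function(N)
    estimate_localization_error(list(fit_at(N)), emccd, n_sim = 150,
                                seed = 7)$mean_um, numeric(1))
  expect_true(all(diff(errs) < 0))            # monotone decreasing ladder
  expect_lt(abs(errs[1] / errs[2] - 2), 0.5)  # quadrupling ~ halves, 25%
  expect_lt(abs(errs[2] / errs[3] - 2), 0.5)
  expect_error(estimate_localization_error(list(fit_at(500)), emccd,
                                           n_sim = 5), "n_sim")
})

test_that("a ~0.015 um localization error yields ~0.03 um immobile steps", {
  # photons chosen so the Gaussian-fit error is near 0.015 um at 160 nm px
  emccd <- emccd_model(offset = 100, gain = 20, read_noise = 0.5)
  fit <- structure(list(x0 = 4.5, y0 = 4.5, sigma = 1.2, photons = 260,
                        background = 1, converged = TRUE),
                   class = "spt_psf_fit")
  est <- estimate_localization_error(list(fit), emccd, n_sim = 200, seed = 3)
  expect_lt(abs(est$mean_um - 0.017), 0.006)
  # radial mean -> per-axis sigma, fed through the simulator
  sigma_axis <- est$mean_um / sqrt(pi / 2)
  cfg <- simulation_config(n_states = 1, D = 0, rate_matrix = matrix(0, 1, 1),
                           loc_sigma = sigma_axis, bleach_rate = 0,
                           max_frames = 101, n_particles = 100, seed = 9)
  r <- unlist(lapply(to_steps(simulate_trajectories(cfg), 0.081), `[[`, "r"))
  expect_gt(mean(r), 0.02)
  expect_lt(mean(r), 0.04)
})

test_that("movie localization recovers rendered positions", {
  set.seed(31)
  traj <- data.frame(particle_id = rep(1:3, each = 4),
                     frame = rep(0:3, 3),
                     x_um = rep(c(1.2, 2.9, 4.1), each = 4),
                     y_um = rep(c(3.8, 1.1, 4.6), each = 4))
  im <- imaging_params(photons = 2000, background = 2)
  mv <- render_movie(traj, im, field_size = 6.4, seed = 5)
  emccd <- emccd_model(im$offset, im$gain, im$read_noise)
  loc <- localize_movie(mv, emccd, threshold = 50)
  expect_equal(nrow(loc), 12)
  for (i in 1:3) {
    sub <- loc[order((loc$x_um - traj$x_um[4 * i])^2)[1:4], ]
    expect_lt(max(abs(sub$x_um - traj$x_um[4 * i])), 0.05)
  }
})
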