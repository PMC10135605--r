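# Synthetic switching-diffusion generator.  Emulates TIRF single-particle
# recordings of enzymes on a substrate surface: 2D Brownian motion whose
# diffusion coefficient switches among a small number of mobility states
# according to a continuous-time Markov chain, Gaussian localization noise,
# and photobleaching-limited track lengths.

#' Default transition-rate matrix of the three-state mobility model
#'
#' Off-diagonal entries are rates in s^-1 from row state to column state;
#' the diagonal is zero.  States are ordered immobile, slow, fast.  The
#' default values lie in the 0.27-2.48 s^-1 range typical for interfacial
#' enzyme mobility switching, with slow<->fast exchange faster than
#' immobile<->fast exchange.
#'
#' @return 3x3 numeric matrix of rates (s^-1).
#' @export
default_rate_matrix <- function() {
  k <- matrix(0, 3, 3)
  k[1, 2] <- 0.80; k[1, 3] <- 0.27
  k[2, 1] <- 0.50; k[2, 3] <- 0.35
  k[3, 1] <- 0.30; k[3, 2] <- 1.20
  dimnames(k) <- list(paste0("s", 1:3), paste0("s", 1:3))
  k
}

#' Stationary distribution of a continuous-time Markov chain
#'
#' @param rate_matrix Square matrix of off-diagonal transition rates (s^-1).
#' @return Probability vector summing to 1 (the left null vector of the
#'   generator).
#' @export
stationary_distribution <- function(rate_matrix) {
  K <- nrow(rate_matrix)
  if (K == 1) return(1)
  Q <- rate_matrix
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0, sum(pi) = 1 as an augmented linear system
  M <- rbind(t(Q), rep(1, K))
  b <- c(rep(0, K), 1)
  pi_hat <- qr.solve(M, b)
  pi_hat <- pmax(pi_hat, 0)
  pi_hat / sum(pi_hat)
}

#' Configuration for the switching-diffusion simulator
#'
#' @param n_states Number of mobility states.
#' @param D Diffusion coefficient per state (um^2/s).  The defaults give an
#'   immobile state (pure localization error), a slow and a fast state.
#' @param rate_matrix Off-diagonal switching rates (s^-1), `n_states` square.
#' @param initial_occupancy Start-state probabilities; default the stationary
#'   distribution of `rate_matrix`.
#' @param loc_sigma Localization noise standard deviation per coordinate (um).
#'   The default 0.015 um yields a mean immobile-state step of about 0.03 um
#'   (`loc_sigma * sqrt(pi)`).
#' @param frame_interval Time between frames (s); default 0.081.
#' @param bleach_rate Photobleaching rate (s^-1) terminating tracks; 0 means
#'   every track runs to `max_frames`.
#' @param n_particles Number of tracks to simulate.
#' @param field_size Side length of the square field of view (um).
#' @param max_frames Hard cap on track length in frames (camera series
#'   length); default 2000.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return Object of class `spt_sim_config`.
#' @export
simulation_config <- function(n_states = 3,
                              D = c(0, 0.01, 0.1),
                              rate_matrix = default_rate_matrix(),
                              initial_occupancy = NULL,
                              loc_sigma = 0.015,
                              frame_interval = 0.081,
                              bleach_rate = 0.2,
                              n_particles = 1000,
                              field_size = 81.92,
                              max_frames = 2000,
                              seed = 1L) {
  rate_matrix <- as.matrix(rate_matrix)
  if (length(D) != n_states)
    stop("length(D) must equal n_states")
  if (any(D < 0)) stop("all diffusion coefficients must be >= 0")
  if (!all(dim(rate_matrix) == c(n_states, n_states)))
    stop("rate_matrix must be n_states x n_states")
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("transition rates must be >= 0")
  if (is.null(initial_occupancy)) {
    initial_occupancy <- if (all(off == 0)) rep(1 / n_states, n_states)
                         else stationary_distribution(rate_matrix)
  }
  if (length(initial_occupancy) != n_states ||
      abs(sum(initial_occupancy) - 1) > 1e-8 || any(initial_occupancy < 0))
    stop("initial_occupancy must be a probability vector over states")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (loc_sigma < 0 || bleach_rate < 0) stop("loc_sigma and bleach_rate must be >= 0")
  if (n_particles < 1 || max_frames < 2) stop("need n_particles >= 1 and max_frames >= 2")
  structure(list(
    n_states = as.integer(n_states), D = as.numeric(D),
    rate_matrix = off, initial_occupancy = as.numeric(initial_occupancy),
    loc_sigma = loc_sigma, frame_interval = frame_interval,
    bleach_rate = bleach_rate, n_particles = as.integer(n_particles),
    field_size = field_size, max_frames = as.integer(max_frames),
    seed = as.integer(seed)
  ), class = "spt_sim_config")
}

# Track length in frames under exponential photobleaching, minimum 2.
draw_track_lengths <- function(n, bleach_rate, frame_interval, max_frames) {
  if (bleach_rate == 0) return(rep(max_frames, n))
  p_bleach <- 1 - exp(-bleach_rate * frame_interval)
  pmin(max_frames, 2L + stats::rgeom(n, p_bleach))
}

#' Simulate per-particle mobility state sequences
#'
#' Each particle's state path is a continuous-time Markov chain with the
#' configured generator, sampled at frame boundaries (so real-time dwell
#' times are exponential, and a frame's state is the state occupied at the
#' frame start).  Track lengths are photobleaching-limited.
#'
#' @param config An [simulation_config()] object.
#' @return List of integer state vectors (1-based), one per particle.
#' @export
simulate_state_paths <- function(config) {
  stopifnot(inherits(config, "spt_sim_config"))
  set.seed(config$seed)
  K <- config$n_states
  exit_rates <- rowSums(config$rate_matrix)
  lens <- draw_track_lengths(config$n_particles, config$bleach_rate,
                             config$frame_interval, config$max_frames)
  t <- config$frame_interval
  lapply(seq_len(config$n_particles), function(p) {
    L <- lens[p]
    s <- sample.int(K, 1, prob = config$initial_occupancy)
    if (K == 1 || all(exit_rates == 0)) return(rep(s, L))
    t_end <- (L - 1) * t
    jump_times <- numeric(0); jump_states <- integer(0)
    now <- 0; cur <- s
    while (TRUE) {
      lam <- exit_rates[cur]
      if (lam == 0) break
      now <- now + stats::rexp(1, lam)
      if (now > t_end) break
      cur <- sample.int(K, 1, prob = config$rate_matrix[cur, ])
      jump_times <- c(jump_times, now); jump_states <- c(jump_states, cur)
    }
    frame_times <- (0:(L - 1)) * t
    idx <- findInterval(frame_times, jump_times)
    c(s, jump_states)[idx + 1L]
  })
}

#' Simulate trajectories from state paths
#'
#' Per-frame 2D displacements are Gaussian with per-axis variance
#' `2 * D[state] * frame_interval`, using the state at the frame start;
#' observed positions add i.i.d. Gaussian localization noise of standard
#' deviation `loc_sigma` per coordinate.  Both true and observed coordinates
#' are retained.
#'
#' @param config An [simulation_config()] object.
#' @param state_paths Output of [simulate_state_paths()]; regenerated from
#'   `config` when `NULL`.
#' @return `data.frame` with columns `particle_id`, `frame` (0-based),
#'   `x_um`, `y_um` (observed), `x_true_um`, `y_true_um`, `state_true`.
#' @export
simulate_trajectories <- function(config, state_paths = NULL) {
  stopifnot(inherits(config, "spt_sim_config"))
  if (is.null(state_paths)) state_paths <- simulate_state_paths(config)
  t <- config$frame_interval
  out <- vector("list", length(state_paths))
  for (p in seq_along(state_paths)) {
    s <- state_paths[[p]]
    L <- length(s)
    sd_step <- sqrt(2 * config$D[s[-L]] * t)
    x0 <- stats::runif(1, 0, config$field_size)
    y0 <- stats::runif(1, 0, config$field_size)
    xt <- cumsum(c(x0, stats::rnorm(L - 1, 0, sd_step)))
    yt <- cumsum(c(y0, stats::rnorm(L - 1, 0, sd_step)))
    xo <- xt + stats::rnorm(L, 0, config$loc_sigma)
    yo <- yt + stats::rnorm(L, 0, config$loc_sigma)
    out[[p]] <- data.frame(
      particle_id = p, frame = 0:(L - 1),
      x_um = xo, y_um = yo, x_true_um = xt, y_true_um = yt,
      state_true = s
    )
  }
  do.call(rbind, out)
}

#' Imaging parameters for movie rendering
#'
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @param photons Expected photons per spot per frame.
#' @param background Expected background photons per pixel per frame.
#' @param gain EMCCD gain (ADU per photon).
#' @param offset Camera offset (ADU).
#' @param read_noise Read noise standard deviation (ADU).
#' @param pixel_size_um Pixel width (um); default 0.160.
#' @return Named list of class `spt_imaging_params`.
#' @export
imaging_params <- function(psf_sigma_px = 1.2, photons = 500, background = 5,
                           gain = 20, offset = 100, read_noise = 5,
                           pixel_size_um = 0.160) {
  stopifnot(psf_sigma_px > 0, photons >= 0, background >= 0, gain > 0,
            offset >= 0, read_noise >= 0, pixel_size_um > 0)
  structure(list(psf_sigma_px = psf_sigma_px, photons = photons,
                 background = background, gain = gain, offset = offset,
                 read_noise = read_noise, pixel_size_um = pixel_size_um),
            class = "spt_imaging_params")
}

# Expected photon image of point emitters: pixel-integrated 2D Gaussian.
# Positions in continuous pixel units (pixel j spans [j-1, j)).
render_spots_photons <- function(nx, ny, x_px, y_px, sigma, photons) {
  img <- matrix(0, ny, nx)
  if (length(x_px) == 0) return(img)
  w <- ceiling(5 * sigma)
  for (i in seq_along(x_px)) {
    jx <- max(1, floor(x_px[i] - w)):min(nx, ceiling(x_px[i] + w))
    jy <- max(1, floor(y_px[i] - w)):min(ny, ceiling(y_px[i] + w))
    if (!length(jx) || !length(jy)) next  # outside field: clipped
    fx <- stats::pnorm(jx, x_px[i], sigma) - stats::pnorm(jx - 1, x_px[i], sigma)
    fy <- stats::pnorm(jy, y_px[i], sigma) - stats::pnorm(jy - 1, y_px[i], sigma)
    img[jy, jx] <- img[jy, jx] + photons[min(i, length(photons))] * outer(fy, fx)
  }
  img
}

#' Render trajectories into a synthetic TIRF movie
#'
#' Each particle is drawn as a pixel-integrated 2D Gaussian PSF; photon
#' images pass through shot noise, EM gain, offset and Gaussian read noise,
#' producing 16-bit frames.  Particles outside the field are silently
#' clipped.  Deterministic under a fixed seed.
#'
#' @param trajectories Trajectory `data.frame` (observed or true coordinates
#'   in um; `x_true_um`/`y_true_um` are used when present so localization
#'   noise arises from the imaging chain itself, not twice).
#' @param imaging An [imaging_params()] object.
#' @param field_size Field of view side (um); sets the image size.
#' @param n_frames Number of frames to render; default the trajectory span.
#' @param seed Integer seed.
#' @return List with `frames` (list of integer matrices), `metadata` list.
#' @export
render_movie <- function(trajectories, imaging = imaging_params(),
                         field_size = 81.92, n_frames = NULL, seed = 1L) {
  stopifnot(inherits(imaging, "spt_imaging_params"))
  set.seed(seed)
  px <- imaging$pixel_size_um
  nx <- ny <- as.integer(ceiling(field_size / px))
  if (is.null(n_frames)) {
    n_frames <- if (nrow(trajectories)) max(trajectories$frame) + 1L else 1L
  }
  xcol <- if ("x_true_um" %in% names(trajectories)) "x_true_um" else "x_um"
  ycol <- if ("y_true_um" %in% names(trajectories)) "y_true_um" else "y_um"
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    rows <- trajectories$frame == f
    lambda <- render_spots_photons(nx, ny,
                                   trajectories[[xcol]][rows] / px,
                                   trajectories[[ycol]][rows] / px,
                                   imaging$psf_sigma_px, imaging$photons) +
      imaging$background
    counts <- matrix(stats::rpois(nx * ny, lambda), ny, nx)
    adu <- imaging$offset + imaging$gain * counts +
      matrix(stats::rnorm(nx * ny, 0, imaging$read_noise), ny, nx)
    frames[[f + 1L]] <- matrix(as.integer(pmin(pmax(round(adu), 0), 65535)),
                               ny, nx)
  }
  list(frames = frames,
       metadata = list(pixel_size_um = px, gain = imaging$gain,
                       offset = imaging$offset, read_noise = imaging$read_noise,
                       psf_sigma_px = imaging$psf_sigma_px,
                       n_frames = n_frames, nx = nx, ny = ny))
}

#' Write a rendered movie as multi-page 16-bit TIFF with a JSON sidecar
#'
#' @param movie Output of [render_movie()].
#' @param path Path of the `.tif` file; the sidecar is `<path>.json`.
#' @param frame_interval_s Frame interval recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, frame_interval_s = 0.081) {
  imgs <- lapply(movie$frames, function(m) m / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  meta <- c(movie$metadata, list(frame_interval_s = frame_interval_s))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie written by [write_movie_tiff()]
#'
#' @param path Path to the `.tif` file.
#' @return List with `frames` (integer matrices, ADU) and `metadata`.
#' @export
read_movie_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(imgs, function(m) matrix(as.integer(round(m * 65535)),
                                            nrow(m), ncol(m)))
  meta_path <- paste0(path, ".json")
  metadata <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  list(frames = frames, metadata = metadata)
}

#' Write / read trajectory tables
#'
#' Trajectory CSVs have columns `particle_id`, `frame` (0-based), `x_um`,
#' `y_um` and optionally `state_true` plus true coordinates (simulation
#' only).
#'
#' @param trajectories Trajectory `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly, or the `data.frame` for the reader.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  need <- c("particle_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory table must have columns ", paste(need, collapse = ", "))
  df[order(df$particle_id, df$frame), , drop = FALSE]
}
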