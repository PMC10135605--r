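# Camera calibration and sub-pixel localization.  The EMCCD model is
# adu = offset + gain * Poisson(photons) + N(0, read_noise); calibration
# inverts it from a particle-free background series via the mean-variance
# relation var(adu) = gain * (mean(adu) - offset) + read_noise^2.

#' Calibrate an EMCCD camera from a background image series
#'
#' Requires a stack of particle-free background frames whose illumination
#' varies across the field and includes (near-)unilluminated pixels: the
#' darkest pixels give the offset and read noise, and the gain is the
#' origin-constrained least-squares slope of per-pixel excess variance
#' against per-pixel mean above offset.  Saturated pixels are excluded.
#'
#' @param background_stack List of frames (matrices, ADU) or 3D array with
#'   frames in the third dimension; at least 10 frames.
#' @param dark_quantile Fraction of darkest pixels used for offset/read-noise
#'   estimation (default 0.02).
#' @param saturation ADU level above which pixels are excluded (default 65000).
#' @return Object of class `spt_emccd` with `offset` (ADU), `gain`
#'   (ADU/photon) and `read_noise` (ADU).
#' @export
calibrate_emccd <- function(background_stack, dark_quantile = 0.02,
                            saturation = 65000) {
  if (is.list(background_stack))
    background_stack <- simplify2array(background_stack)
  stopifnot(length(dim(background_stack)) == 3)
  nf <- dim(background_stack)[3]
  if (nf < 10) stop("need >= 10 background frames")
  m <- apply(background_stack, c(1, 2), mean)
  v <- apply(background_stack, c(1, 2), var)
  ok <- m < saturation
  m <- m[ok]; v <- v[ok]
  if (stats::sd(m) < 1e-9 || all(v < 1e-12))
    stop("background stack is constant: gain is indeterminate")
  dark <- m <= stats::quantile(m, dark_quantile)
  offset <- stats::median(m[dark])
  rn2 <- max(stats::median(v[dark]), 0)
  lit <- m > offset + 3 * sqrt(rn2 / nf + 1e-12)
  if (sum(lit) < 10)
    stop("background stack has no illuminated pixels: gain is indeterminate")
  x <- m[lit] - offset
  y <- v[lit] - rn2
  gain <- sum(x * y) / sum(x * x)
  if (!is.finite(gain) || gain <= 0)
    stop("gain estimate is not positive; check the background stack")
  structure(list(offset = offset, gain = gain, read_noise = sqrt(rn2)),
            class = "spt_emccd")
}

#' Construct an EMCCD model from known parameters
#' @param offset Camera offset (ADU).
#' @param gain ADU per photon.
#' @param read_noise Read-noise standard deviation (ADU).
#' @return Object of class `spt_emccd`.
#' @export
emccd_model <- function(offset, gain, read_noise) {
  stopifnot(gain > 0, read_noise >= 0)
  structure(list(offset = offset, gain = gain, read_noise = read_noise),
            class = "spt_emccd")
}

#' Convert a raw frame (ADU) to photon counts
#' @param frame Matrix of ADU values.
#' @param emccd An `spt_emccd` model.
#' @return Matrix of photon estimates (can be slightly negative from noise).
#' @export
adu_to_photons <- function(frame, emccd) {
  stopifnot(inherits(emccd, "spt_emccd"))
  (frame - emccd$offset) / emccd$gain
}

#' Detect candidate spots as thresholded local maxima
#'
#' Local maxima of the photon image above `threshold` are kept, then
#' non-maximum suppression removes any candidate within `min_separation`
#' pixels of a brighter one (close pairs merge into the brighter candidate).
#'
#' @param frame Matrix in photon units (use [adu_to_photons()] first).
#' @param min_separation Minimum distance between detections (px).
#' @param threshold Minimum peak height (photons above zero).
#' @return `data.frame` with `x_px`, `y_px` (pixel-center coordinates,
#'   continuous convention: pixel j has center j - 0.5) and `peak_photons`;
#'   zero rows when nothing is found.
#' @export
detect_spots <- function(frame, min_separation = 5, threshold = 10) {
  ny <- nrow(frame); nx <- ncol(frame)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      peak_photons = numeric(0))
  if (ny < 3 || nx < 3) return(empty)
  inner <- frame[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (inner >= frame[2:(ny - 1) + dy, 2:(nx - 1) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                     peak = inner[is_max])
  cand <- cand[order(-cand$peak, cand$row, cand$col), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
    keep[i] <- all(d2 >= min_separation^2)
  }
  cand <- cand[keep, ]
  data.frame(x_px = cand$col - 0.5, y_px = cand$row - 0.5,
             peak_photons = cand$peak)
}

# Pixel-integrated symmetric 2D Gaussian + constant background on a crop.
psf_model_image <- function(par, nx, ny) {
  fx <- stats::pnorm(1:nx, par[["x0"]], par[["sigma"]]) -
        stats::pnorm(0:(nx - 1), par[["x0"]], par[["sigma"]])
  fy <- stats::pnorm(1:ny, par[["y0"]], par[["sigma"]]) -
        stats::pnorm(0:(ny - 1), par[["y0"]], par[["sigma"]])
  par[["N"]] * outer(fy, fx) + par[["bg"]]
}

#' Fit a symmetric 2D Gaussian PSF with constant background to a crop
#'
#' Least-squares fit (Levenberg-Marquardt) of a pixel-integrated circular
#' Gaussian; the photon count `N` is the total flux of the spot.
#'
#' @param crop Square matrix in photon units (default workflow: 9x9 px).
#' @param initial_guess Optional named list/vector with `x0`, `y0`, `sigma`,
#'   `N`, `bg` (crop coordinates, pixel units).  Defaults are derived from
#'   the crop.
#' @return Object of class `spt_psf_fit`: `x0`, `y0` (px, crop frame),
#'   `sigma` (px), `photons`, `background` (photons/px), `converged`.
#' @export
fit_psf <- function(crop, initial_guess = NULL) {
  ny <- nrow(crop); nx <- ncol(crop)
  if (is.null(initial_guess)) {
    bg0 <- stats::median(crop)
    w <- pmax(crop - bg0, 0)
    tot <- sum(w)
    if (tot <= 0) { w <- matrix(1, ny, nx); tot <- sum(w) }
    x0 <- sum(t(w) * (1:nx - 0.5)) / tot
    y0 <- sum(w * (1:ny - 0.5)) / tot
    initial_guess <- list(x0 = x0, y0 = y0, sigma = 1.3,
                          N = max(tot, 1), bg = bg0)
  }
  z <- as.vector(crop)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(initial_guess[c("x0", "y0", "sigma", "N", "bg")]),
      fn = function(p) as.vector(psf_model_image(p, nx, ny)) - z,
      lower = c(-1, -1, 0.2, 0, -Inf),
      upper = c(nx + 1, ny + 1, max(nx, ny), Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$deviance)) {
    p <- unlist(initial_guess)
    return(structure(list(x0 = p[["x0"]], y0 = p[["y0"]], sigma = p[["sigma"]],
                          photons = p[["N"]], background = p[["bg"]],
                          converged = FALSE), class = "spt_psf_fit"))
  }
  p <- fit$par
  structure(list(x0 = p[["x0"]], y0 = p[["y0"]], sigma = p[["sigma"]],
                 photons = p[["N"]], background = p[["bg"]],
                 converged = fit$info %in% 1:4 && p[["sigma"]] > 0.2),
            class = "spt_psf_fit")
}

# Simulate one noisy crop of a PSF through the EMCCD model, in photon units
# after conversion back (what the fitting sees in the real workflow).
simulate_psf_crop <- function(par, nx, ny, emccd) {
  lambda <- psf_model_image(par, nx, ny)
  counts <- matrix(stats::rpois(nx * ny, pmax(lambda, 0)), ny, nx)
  adu <- emccd$offset + emccd$gain * counts +
    matrix(stats::rnorm(nx * ny, 0, emccd$read_noise), ny, nx)
  adu_to_photons(adu, emccd)
}

#' Estimate the localization error by simulation from fitted PSFs
#'
#' For every converged PSF fit, `n_sim` synthetic spots with the fitted
#' photon count, width and background are generated at known sub-pixel
#' centers through the EMCCD noise model, re-localized with the same
#' Gaussian fit, and the Euclidean distance to the true center recorded.
#' The mean of the pooled error distribution is the localization error.
#'
#' @param psf_fits List of `spt_psf_fit` objects (non-converged are skipped).
#' @param emccd An `spt_emccd` model.
#' @param n_sim Simulations per fit (>= 10).
#' @param crop_size Side of the simulated crop (px).
#' @param pixel_size_um Pixel width (um), default 0.160.
#' @param seed Integer seed.
#' @return List with `errors_um` (pooled distribution) and `mean_um`.
#' @export
estimate_localization_error <- function(psf_fits, emccd, n_sim = 100,
                                        crop_size = 9, pixel_size_um = 0.160,
                                        seed = 1L) {
  if (inherits(psf_fits, "spt_psf_fit")) psf_fits <- list(psf_fits)
  if (n_sim < 10) stop("n_sim must be >= 10")
  fits <- Filter(function(f) isTRUE(f$converged), psf_fits)
  if (length(fits) == 0) stop("need at least one converged PSF fit")
  set.seed(seed)
  ctr <- crop_size / 2
  errors <- unlist(lapply(fits, function(f) {
    errs <- numeric(n_sim)
    for (i in seq_len(n_sim)) {
      x0 <- ctr + stats::runif(1, -0.5, 0.5)
      y0 <- ctr + stats::runif(1, -0.5, 0.5)
      par <- c(x0 = x0, y0 = y0, sigma = f$sigma, N = f$photons,
               bg = max(f$background, 0))
      crop <- simulate_psf_crop(par, crop_size, crop_size, emccd)
      refit <- fit_psf(crop, initial_guess = list(x0 = ctr, y0 = ctr,
                                                  sigma = f$sigma,
                                                  N = f$photons,
                                                  bg = max(f$background, 0)))
      errs[i] <- sqrt((refit$x0 - x0)^2 + (refit$y0 - y0)^2)
    }
    errs
  }))
  errors_um <- errors * pixel_size_um
  list(errors_um = errors_um, mean_um = mean(errors_um))
}

#' Localize particles in a movie
#'
#' Runs spot detection and PSF fitting on every frame and returns a
#' localization table in the format consumed by [link_trajectories()].
#'
#' @param movie List with `frames` (ADU matrices) as from [read_movie_tiff()]
#'   or [render_movie()].
#' @param emccd An `spt_emccd` model.
#' @param min_separation,threshold Passed to [detect_spots()].
#' @param crop_size Fitting crop side (px, odd), default 9.
#' @param pixel_size_um Pixel width (um).
#' @return `data.frame` with columns `frame` (0-based), `x_px`, `y_px`,
#'   `x_um`, `y_um`, `photons`, `bg`, `width_px`.
#' @export
localize_movie <- function(movie, emccd, min_separation = 5, threshold = 10,
                           crop_size = 9, pixel_size_um = 0.160) {
  half <- (crop_size - 1) %/% 2
  rows <- list()
  for (f in seq_along(movie$frames)) {
    ph <- adu_to_photons(movie$frames[[f]], emccd)
    ny <- nrow(ph); nx <- ncol(ph)
    spots <- detect_spots(ph, min_separation, threshold)
    for (s in seq_len(nrow(spots))) {
      cx <- round(spots$x_px[s] + 0.5); cy <- round(spots$y_px[s] + 0.5)
      if (cx - half < 1 || cx + half > nx || cy - half < 1 || cy + half > ny)
        next
      crop <- ph[(cy - half):(cy + half), (cx - half):(cx + half)]
      fit <- fit_psf(crop)
      if (!fit$converged) next
      x_px <- fit$x0 + (cx - half - 1)
      y_px <- fit$y0 + (cy - half - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f - 1L, x_px = x_px, y_px = y_px,
        x_um = x_px * pixel_size_um, y_um = y_px * pixel_size_um,
        photons = fit$photons, bg = fit$background, width_px = fit$sigma)
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      photons = numeric(0), bg = numeric(0),
                      width_px = numeric(0)))
  do.call(rbind, rows)
}
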