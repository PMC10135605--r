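# Diffusion-coefficient estimation from step lengths.  For 2D Brownian
# motion the step length at lag t follows p(r, t, D) = r/(2Dt) exp(-r^2/4Dt);
# the per-trajectory maximum-likelihood estimate is the closed form
# D_hat = sum(r^2) / (4 n t), used without binning.

#' Maximum-likelihood diffusion coefficient of one step trace
#'
#' @param step_trace A step trace (list with `r` in um and `t` in s) as
#'   produced by [to_steps()], or a numeric vector of step lengths (then
#'   `t` must be given).
#' @param t Frame interval (s); taken from the trace when omitted.
#' @return List of class `spt_diffusion`: `particle_id`, `D` (um^2/s),
#'   `n_steps`, `log10D` and `degenerate` (TRUE when all steps are zero,
#'   giving D = 0).
#' @export
mle_diffusion <- function(step_trace, t = NULL) {
  if (is.numeric(step_trace))
    step_trace <- list(particle_id = NA_integer_, r = step_trace, t = t)
  r <- step_trace$r
  t <- if (is.null(t)) step_trace$t else t
  if (length(r) < 1) stop("need at least one step")
  if (any(r < 0)) stop("step lengths must be >= 0")
  n <- length(r)
  D <- sum(r^2) / (4 * n * t)
  structure(list(particle_id = step_trace$particle_id, D = D, n_steps = n,
                 log10D = if (D > 0) log10(D) else -Inf,
                 degenerate = all(r == 0)),
            class = "spt_diffusion")
}

#' Per-trajectory diffusion coefficients for a set of step traces
#'
#' @param step_traces List of step traces from [to_steps()]; empty traces
#'   are skipped.
#' @param t Frame interval override (s).
#' @return `data.frame` with `particle_id`, `n_steps`, `D_um2_s`, `log10D`,
#'   `degenerate`.
#' @export
estimate_diffusion <- function(step_traces, t = NULL) {
  step_traces <- Filter(function(s) length(s$r) >= 1, step_traces)
  rows <- lapply(step_traces, function(s) {
    e <- mle_diffusion(s, t)
    data.frame(particle_id = e$particle_id, n_steps = e$n_steps,
               D_um2_s = e$D, log10D = e$log10D, degenerate = e$degenerate)
  })
  do.call(rbind, rows)
}

#' Histogram of log10 diffusion coefficients
#'
#' Zero estimates (immobile within noise) cannot be placed on a log axis
#' and are reported separately.
#'
#' @param estimates `data.frame` from [estimate_diffusion()].
#' @param bins Number of bins.
#' @return List with `density` (normalized so the masses sum to 1),
#'   `counts`, `breaks`, `mids` and `n_zero`.
#' @export
logd_histogram <- function(estimates, bins = 30) {
  if (is.null(estimates) || nrow(estimates) == 0) stop("no estimates given")
  x <- estimates$log10D[is.finite(estimates$log10D)]
  n_zero <- sum(!is.finite(estimates$log10D))
  if (length(x) == 0) stop("all estimates are zero; nothing to histogram")
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(density = h$counts / sum(h$counts), counts = h$counts,
       breaks = h$breaks, mids = h$mids, n_zero = n_zero)
}

# Weighted maximum-likelihood fit of a gamma distribution.  Newton iteration
# on the shape using log(a) - digamma(a) = log(mean) - mean(log), with the
# standard closed-form starting value.
gamma_wmle <- function(r, w = NULL, logr = NULL) {
  if (is.null(w)) w <- rep(1, length(r))
  if (is.null(logr)) logr <- log(r)
  W <- sum(w)
  m <- sum(w * r) / W
  s <- log(m) - sum(w * logr) / W
  s <- max(s, 1e-10)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:100) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    a_new <- a - f / fp
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-12 * a) { a <- a_new; break }
    a <- a_new
  }
  list(shape = a, scale = m / a)
}

#' Fit a gamma mixture to pooled step lengths by EM
#'
#' Models the total observed step-length distribution as a K-component
#' gamma mixture.  Initialization is a quantile split with per-block
#' method-of-moments; the M-step uses weighted gamma maximum likelihood.
#'
#' @param steps Numeric vector of step lengths (um), all > 0.
#' @param n_components K in 1..4.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @return List of class `spt_gamma_mixture`: `weights`, `shape`, `scale`
#'   (each length K, ordered by increasing mean), `loglik`, `loglik_trace`,
#'   `converged`, `n_iter`.
#' @export
fit_gamma_mixture <- function(steps, n_components, max_iter = 500,
                              tol = 1e-8) {
  if (any(steps <= 0)) stop("steps must be > 0 (floor zeros upstream)")
  if (length(steps) < 100) stop("need >= 100 steps")
  K <- as.integer(n_components)
  stopifnot(K >= 1, K <= 4)
  r <- as.numeric(steps); logr <- log(r); n <- length(r)
  qs <- stats::quantile(r, probs = seq(0, 1, length.out = K + 1))
  grp <- cut(r, breaks = unique(c(-Inf, qs[-c(1, K + 1)], Inf)),
             labels = FALSE)
  shape <- scale <- weights <- numeric(K)
  for (k in seq_len(K)) {
    rk <- r[grp == min(k, max(grp))]
    mk <- mean(rk); vk <- max(stats::var(rk), 1e-12)
    shape[k] <- max(mk^2 / vk, 0.1); scale[k] <- vk / mk
    weights[k] <- length(rk) / n
  }
  weights <- weights / sum(weights)
  loglik_trace <- numeric(0); ll_old <- -Inf; converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k)
      log(weights[k]) + stats::dgamma(r, shape[k], scale = scale[k],
                                      log = TRUE), numeric(n))
    mx <- apply(logd, 1, max)
    p <- exp(logd - mx)
    rs <- rowSums(p)
    ll <- sum(mx + log(rs))
    loglik_trace <- c(loglik_trace, ll)
    resp <- p / rs
    weights <- colSums(resp) / n
    for (k in seq_len(K)) {
      fit <- gamma_wmle(r, resp[, k], logr)
      shape[k] <- fit$shape; scale[k] <- fit$scale
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ord <- order(shape * scale)
  structure(list(weights = weights[ord], shape = shape[ord],
                 scale = scale[ord], loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, converged = converged,
                 n_iter = it),
            class = "spt_gamma_mixture")
}
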