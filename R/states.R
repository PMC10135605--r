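# Hidden Markov modeling of step-length traces.  One shared parameter set
# (per-state gamma step-length emissions and a per-frame transition matrix)
# is fitted jointly over all traces of a condition by Baum-Welch; the number
# of mobility states is chosen by BIC over 1-4 states; Viterbi decoding
# yields contiguous dwell segments used downstream for kinetics.

STEP_FLOOR_UM <- 1e-4  # zero steps are floored so gamma densities stay finite

prepare_step_data <- function(step_traces, min_steps = 1L) {
  step_traces <- Filter(function(s) length(s$r) >= min_steps, step_traces)
  if (length(step_traces) == 0) stop("no usable step traces")
  r <- unlist(lapply(step_traces, `[[`, "r"))
  r <- pmax(r, STEP_FLOOR_UM)
  lens <- vapply(step_traces, function(s) length(s$r), integer(1))
  list(traces = step_traces, r = r, lens = lens,
       t = step_traces[[1]]$t,
       ids = vapply(step_traces, function(s) s$particle_id[1], numeric(1)))
}

hmm_init_params <- function(r, K, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qs <- stats::quantile(r, probs = seq(0, 1, length.out = K + 1))
  grp <- findInterval(r, unique(qs), rightmost.closed = TRUE)
  grp <- pmin(pmax(grp, 1), K)
  shape <- scale <- numeric(K)
  for (k in seq_len(K)) {
    rk <- r[grp == k]
    if (length(rk) < 2) rk <- r
    mk <- mean(rk); vk <- max(stats::var(rk), 1e-12)
    shape[k] <- max(mk^2 / vk, 0.1); scale[k] <- vk / mk
  }
  if (jitter > 0) {
    shape <- shape * exp(stats::rnorm(K, 0, jitter))
    scale <- scale * exp(stats::rnorm(K, 0, jitter))
  }
  A <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  list(pi = rep(1 / K, K), A = A, shape = shape, scale = scale)
}

#' Fit a gamma-emission hidden Markov model to step traces
#'
#' Baum-Welch over all traces jointly (shared emissions and transition
#' matrix, per-trace forward-backward).  Emissions are gamma densities on
#' the raw step length; zero steps are floored at 1e-4 um.  States are
#' reordered by increasing mean step after fitting so labels are
#' identifiable (immobile, slow, fast for a 3-state model).
#'
#' @param step_traces List of step traces ([to_steps()] output).
#' @param n_states Number of hidden states (1..4).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum Baum-Welch iterations (default 500).
#' @param seed Seed for restart jitter.
#' @param min_steps Traces with fewer steps are dropped before fitting.
#' @return Object of class `spt_hmm`: `n_states`, `initial_probs`,
#'   `transition_matrix` (per-frame probabilities), `emissions`
#'   (`data.frame` shape, scale, mean_step), `log_likelihood`,
#'   `loglik_trace`, `n_params`, `bic`, `n_obs`, `converged`.
#' @export
fit_hmm <- function(step_traces, n_states, tol = 1e-8, max_iter = 500,
                    seed = 1L, min_steps = 1L) {
  K <- as.integer(n_states)
  stopifnot(K >= 1, K <= 4)
  dat <- prepare_step_data(step_traces, min_steps)
  r <- dat$r; lens <- dat$lens; n <- length(r)
  logr <- log(r)
  for (restart in 0:5) {
    par <- hmm_init_params(r, K, jitter = if (restart > 0) 0.3 else 0,
                           seed = seed + restart)
    ll_trace <- numeric(0); ll_old <- -Inf
    collapsed <- FALSE; converged <- FALSE
    for (it in seq_len(max_iter)) {
      logB <- vapply(seq_len(K), function(k)
        stats::dgamma(r, par$shape[k], scale = par$scale[k], log = TRUE),
        numeric(n))
      if (!all(is.finite(logB))) { collapsed <- TRUE; break }
      es <- hmm_estep_cpp(logB, lens, par$pi, par$A)
      ll_trace <- c(ll_trace, es$loglik)
      par$pi <- es$init / sum(es$init)
      if (K > 1) {
        A <- es$xi
        rs <- rowSums(A)
        rs[rs == 0] <- 1
        par$A <- A / rs
      }
      for (k in seq_len(K)) {
        fit <- gamma_wmle(r, es$post[, k], logr)
        par$shape[k] <- fit$shape; par$scale[k] <- fit$scale
      }
      if (any(par$scale < 1e-10) || any(par$shape > 1e8)) {
        collapsed <- TRUE; break
      }
      if (is.finite(ll_old) &&
          abs(es$loglik - ll_old) < tol * abs(ll_old)) {
        converged <- TRUE; break
      }
      ll_old <- es$loglik
    }
    if (!collapsed) break
    if (restart == 5) stop("HMM emission collapse persisted over 5 restarts")
  }
  means <- par$shape * par$scale
  ord <- order(means)
  emissions <- data.frame(state = seq_len(K), shape = par$shape[ord],
                          scale = par$scale[ord], mean_step = means[ord])
  A <- par$A[ord, ord, drop = FALSE]
  pi0 <- par$pi[ord]
  n_params <- 2 * K + K * (K - 1) + (K - 1)
  ll <- ll_trace[length(ll_trace)]
  structure(list(
    n_states = K, initial_probs = pi0, transition_matrix = A,
    emissions = emissions, log_likelihood = ll, loglik_trace = ll_trace,
    n_params = n_params, bic = -2 * ll + n_params * log(n),
    n_obs = n, n_traces = length(lens), frame_interval = dat$t,
    converged = converged
  ), class = "spt_hmm")
}

matrix_exp <- function(M, order = 30) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(order)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

#' Sample step traces from a gamma-emission hidden Markov model
#'
#' Generates data from the HMM model class itself: a latent state chain
#' discretized from continuous-time rates (per-frame transition matrix
#' `expm(Q t)`), with per-step gamma step lengths.  This is the generator
#' used to validate model selection, since such data are exactly within the
#' fitted family; position-level Brownian simulation
#' ([simulate_trajectories()]) instead produces Rayleigh-distributed steps
#' that gamma emissions only approximate.
#'
#' @param n_traces Number of traces.
#' @param mean_steps Per-state mean step lengths (um), ascending.  The
#'   defaults (0.03, 0.09, 0.2) are the immobile/slow/fast scales typical
#'   of interfacial enzyme mobility.
#' @param shape Gamma shape per state (recycled); default 3.6, the shape a
#'   gamma fit assigns to a Rayleigh-width step distribution.
#' @param rate_matrix Switching rates (s^-1), off-diagonal.
#' @param frame_interval Frame interval t (s).
#' @param bleach_rate Track-termination rate (s^-1) as in the simulator.
#' @param max_frames Track-length cap in frames.
#' @param seed Integer seed.
#' @return List of step traces (as [to_steps()] produces) with an extra
#'   `states` element holding the generating state sequence.
#' @export
simulate_hmm_steps <- function(n_traces, mean_steps = c(0.03, 0.09, 0.2),
                               shape = 3.6,
                               rate_matrix = default_rate_matrix(),
                               frame_interval = 0.081, bleach_rate = 0.2,
                               max_frames = 2000, seed = 1L) {
  K <- length(mean_steps)
  shape <- rep_len(shape, K)
  scale <- mean_steps / shape
  Q <- as.matrix(rate_matrix)
  stopifnot(all(dim(Q) == K))
  diag(Q) <- 0
  pi0 <- if (all(Q == 0)) rep(1 / K, K) else stationary_distribution(Q)
  diag(Q) <- -rowSums(Q)
  A <- matrix_exp(Q * frame_interval)
  A <- pmax(A, 0) / rowSums(pmax(A, 0))
  set.seed(seed)
  lens <- draw_track_lengths(n_traces, bleach_rate, frame_interval,
                             max_frames) - 1L  # steps, not positions
  lapply(seq_len(n_traces), function(p) {
    n <- max(lens[p], 1L)
    s <- integer(n)
    s[1] <- sample.int(K, 1, prob = pi0)
    if (n > 1) for (i in 2:n) s[i] <- sample.int(K, 1, prob = A[s[i - 1], ])
    list(particle_id = p, r = stats::rgamma(n, shape[s], scale = scale[s]),
         t = frame_interval, states = s)
  })
}

#' Select the number of mobility states by BIC
#'
#' Fits HMMs with 1..4 states and returns the model minimizing the Bayesian
#' information criterion (ties go to the smaller model).
#'
#' @param step_traces List of step traces.
#' @param candidates Integer vector of state counts to try (default 1:4).
#' @param ... Passed to [fit_hmm()].
#' @return List with `best` (an `spt_hmm`), `n_states` and `bic_table`
#'   (`data.frame` n_states, log_likelihood, n_params, bic, converged).
#' @export
select_n_states <- function(step_traces, candidates = 1:4, ...) {
  fits <- lapply(candidates, function(K) fit_hmm(step_traces, K, ...))
  tab <- data.frame(
    n_states = candidates,
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  best_i <- which(tab$bic <= min(tab$bic) + 1e-9)[1]  # ties: fewer states
  list(best = fits[[best_i]], n_states = candidates[best_i], bic_table = tab,
       fits = fits)
}

#' Viterbi segmentation of step traces
#'
#' Decodes the most probable state path of each trace under a fitted model
#' and derives contiguous dwell segments.  Each segment carries its state,
#' start step, number of steps, duration in seconds, the model's idealized
#' step (state mean) and the segment's observed mean step.
#'
#' @param model An `spt_hmm` from [fit_hmm()].
#' @param step_traces List of step traces (or a single trace).
#' @return List of `spt_segmented` objects: `particle_id`, `states`
#'   (per-step Viterbi state), `r` (floored observed steps), `segments`
#'   (`data.frame` state, start, n_steps, duration_s, idealized_r,
#'   mean_r), `t`.
#' @export
segment_traces <- function(model, step_traces) {
  stopifnot(inherits(model, "spt_hmm"))
  if (!is.null(step_traces$r)) step_traces <- list(step_traces)
  dat <- prepare_step_data(step_traces)
  K <- model$n_states
  n <- length(dat$r)
  logB <- vapply(seq_len(K), function(k)
    stats::dgamma(dat$r, model$emissions$shape[k],
                  scale = model$emissions$scale[k], log = TRUE), numeric(n))
  logB <- matrix(logB, nrow = n)
  logA <- log(pmax(model$transition_matrix, 1e-300))
  logpi <- log(pmax(model$initial_probs, 1e-300))
  path <- hmm_viterbi_cpp(logB, dat$lens, logpi, matrix(logA, K, K))
  offs <- cumsum(c(0, dat$lens))
  t <- model$frame_interval
  out <- lapply(seq_along(dat$lens), function(i) {
    s <- path[(offs[i] + 1):offs[i + 1]]
    r <- dat$r[(offs[i] + 1):offs[i + 1]]
    runs <- rle(s)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    segments <- data.frame(
      state = runs$values, start = starts, n_steps = runs$lengths,
      duration_s = runs$lengths * t,
      idealized_r = model$emissions$mean_step[runs$values],
      mean_r = vapply(seq_along(starts), function(j)
        mean(r[starts[j]:ends[j]]), numeric(1))
    )
    structure(list(particle_id = dat$ids[i], states = s, r = r,
                   segments = segments, t = t), class = "spt_segmented")
  })
  out
}

#' Per-state occupancy of segmented traces
#'
#' Fraction of all decoded steps spent in each state; sums to 1.
#'
#' @param segmented List of `spt_segmented` objects.
#' @param n_states Number of states (inferred from the data when omitted).
#' @return Named numeric vector of fractions.
#' @export
occupancy <- function(segmented, n_states = NULL) {
  states <- unlist(lapply(segmented, `[[`, "states"))
  if (is.null(n_states)) n_states <- max(states)
  counts <- tabulate(states, nbins = n_states)
  stats::setNames(counts / sum(counts), paste0("state", seq_len(n_states)))
}

#' Histogram of idealized step lengths with a three-Gaussian fit
#'
#' Pools each decoded step's segment-mean step length (so the histogram is
#' occupancy-weighted) and fits a three-component Gaussian mixture to the
#' histogram by least squares, reporting the component means.
#'
#' @param segmented List of `spt_segmented` objects from a 3-state model.
#' @param bins Number of histogram bins.
#' @param init_means Optional starting component means (um).
#' @return List with `mids`, `density`, `breaks`, `fit` (`data.frame`
#'   weight, mean, sd or NULL), `fit_ok`, and `degenerate` (TRUE when fewer
#'   than 3 states are present, in which case no fit is attempted).
#' @export
idealized_step_histogram <- function(segmented, bins = 60,
                                     init_means = NULL) {
  seg_all <- do.call(rbind, lapply(segmented, `[[`, "segments"))
  x <- rep(seg_all$mean_r, seg_all$n_steps)
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  dens <- h$density
  out <- list(mids = h$mids, density = dens, breaks = h$breaks,
              fit = NULL, fit_ok = FALSE,
              degenerate = length(unique(seg_all$state)) < 3)
  if (out$degenerate) return(out)
  if (is.null(init_means)) {
    init_means <- vapply(split(rep(seg_all$mean_r, seg_all$n_steps),
                               rep(seg_all$state, seg_all$n_steps)),
                         mean, numeric(1))
    init_means <- sort(init_means)[1:3]
  }
  occ <- tabulate(rep(seg_all$state, seg_all$n_steps), 3)
  w0 <- occ / sum(occ)
  p0 <- c(w1 = w0[1], w2 = w0[2], w3 = w0[3],
          m1 = init_means[1], m2 = init_means[2], m3 = init_means[3],
          s1 = diff(range(x)) / 20, s2 = diff(range(x)) / 20,
          s3 = diff(range(x)) / 10)
  mixfun <- function(p, xx)
    p[1] * stats::dnorm(xx, p[4], abs(p[7])) +
    p[2] * stats::dnorm(xx, p[5], abs(p[8])) +
    p[3] * stats::dnorm(xx, p[6], abs(p[9]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) mixfun(p, h$mids) - dens,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (!is.null(fit) && all(is.finite(fit$par))) {
    p <- fit$par
    comp <- data.frame(weight = abs(p[1:3]) / sum(abs(p[1:3])),
                       mean = p[4:6], sd = abs(p[7:9]))
    comp <- comp[order(comp$mean), ]
    rownames(comp) <- NULL
    out$fit <- comp
    out$fit_ok <- TRUE
  }
  out
}
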