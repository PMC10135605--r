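# Shared fixtures: all synthetic, generated in code at test time.

# Step lengths of 2D Brownian motion with localization noise at lag t:
# Rayleigh with per-axis sd sqrt(2 D t + 2 sigma^2) (r^2 is exponential).
rayleigh_steps <- function(n, D, t = 0.081, loc_sigma = 0) {
  s2 <- 2 * D * t + 2 * loc_sigma^2
  sqrt(-2 * s2 * log(stats::runif(n)))
}

# Step traces drawn from the model's own step-length density
# p(r, t, D) = r/(2Dt) exp(-r^2/(4Dt)).
model_density_steps <- function(n, D, t = 0.081) {
  sqrt(-4 * D * t * log(stats::runif(n)))
}

# Minimal segmented-trace object (matches segment_traces() output shape).
make_segmented <- function(states_per_step, r = NULL, t = 0.081,
                           particle_id = 1) {
  runs <- rle(states_per_step)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  if (is.null(r)) r <- rep(0.05, length(states_per_step))
  segments <- data.frame(
    state = runs$values, start = starts, n_steps = runs$lengths,
    duration_s = runs$lengths * t,
    idealized_r = NA_real_,
    mean_r = vapply(seq_along(starts), function(j)
      mean(r[starts[j]:ends[j]]), numeric(1)))
  structure(list(particle_id = particle_id, states = states_per_step,
                 r = r, segments = segments, t = t),
            class = "spt_segmented")
}

# Hand-built HMM object for decoder tests.
make_hmm <- function(mean_steps, shape = 50, A = NULL, t = 0.081) {
  K <- length(mean_steps)
  if (is.null(A)) {
    A <- matrix(0.1 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.9 else 1
  }
  structure(list(
    n_states = K, initial_probs = rep(1 / K, K), transition_matrix = A,
    emissions = data.frame(state = seq_len(K), shape = rep(shape, K),
                           scale = mean_steps / shape,
                           mean_step = mean_steps),
    log_likelihood = NA_real_, loglik_trace = numeric(0),
    n_params = 2 * K + K * (K - 1) + (K - 1), bic = NA_real_,
    n_obs = NA_integer_, n_traces = NA_integer_, frame_interval = t,
    converged = TRUE), class = "spt_hmm")
}

expect_monotone_loglik <- function(trace, rel_tol = 1e-6) {
  if (length(trace) < 2) return(invisible(TRUE))
  dips <- diff(trace) / pmax(abs(trace[-length(trace)]), 1)
  expect_true(all(dips > -rel_tol))
}
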