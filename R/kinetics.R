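# Transition kinetics from segmented traces: transition density plots
# (TDPs), cluster assignment of transition events, dwell-time rate fitting
# with right-censoring for bleach-terminated dwells, and transition-state
# theory (Eyring) activation and free energies.

#' Extract transition events and censored dwells from segmented traces
#'
#' One event per adjacent segment pair: the state before and after, the mean
#' observed step of each segment (the TDP coordinates), and the dwell time
#' of the preceding segment.  The terminal segment of every trace ends by
#' track termination (photobleaching), not by a transition, so its dwell is
#' recorded separately as right-censored.
#'
#' @param segmented List of `spt_segmented` objects from [segment_traces()].
#' @return List with `events` (`data.frame` particle_id, state_before,
#'   state_after, mean_step_before, mean_step_after, dwell_before) and
#'   `censored` (`data.frame` particle_id, state, dwell).
#' @export
extract_transitions <- function(segmented) {
  ev <- list(); cs <- list()
  for (tr in segmented) {
    seg <- tr$segments
    ns <- nrow(seg)
    if (ns > 1) {
      j <- seq_len(ns - 1)
      ev[[length(ev) + 1]] <- data.frame(
        particle_id = tr$particle_id,
        state_before = seg$state[j], state_after = seg$state[j + 1],
        mean_step_before = seg$mean_r[j], mean_step_after = seg$mean_r[j + 1],
        dwell_before = seg$duration_s[j])
    }
    cs[[length(cs) + 1]] <- data.frame(particle_id = tr$particle_id,
                                       state = seg$state[ns],
                                       dwell = seg$duration_s[ns])
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(particle_id = numeric(0), state_before = integer(0),
               state_after = integer(0), mean_step_before = numeric(0),
               mean_step_after = numeric(0), dwell_before = numeric(0))
  censored <- do.call(rbind, cs)
  rownames(events) <- rownames(censored) <- NULL
  list(events = events, censored = censored)
}

#' Cluster a transition density plot into ordered state pairs
#'
#' K-means with k = n_states*(n_states-1) on the (mean step before, mean
#' step after) plane initializes a two-dimensional Gaussian mixture model;
#' events are assigned by maximum responsibility and clusters are mapped to
#' ordered state pairs by proximity to the grid of per-state mean steps.
#'
#' @param events Event `data.frame` from [extract_transitions()].
#' @param n_states Number of mobility states.
#' @param state_means Per-state mean step (um); estimated from the events
#'   when omitted.
#' @param seed Seed for the k-means initialization.
#' @return `events` with added columns `cluster`, `pair_before`,
#'   `pair_after` (the cluster's ordered state pair).
#' @export
cluster_tdp <- function(events, n_states, state_means = NULL, seed = 1L) {
  k <- n_states * (n_states - 1)
  if (nrow(events) < k)
    stop("need at least n_states*(n_states-1) = ", k, " events")
  X <- cbind(events$mean_step_before, events$mean_step_after)
  if (is.null(state_means))
    state_means <- vapply(split(events$mean_step_before, events$state_before),
                          mean, numeric(1))[as.character(seq_len(n_states))]
  set.seed(seed)
  pair_grid <- expand.grid(i = seq_len(n_states), j = seq_len(n_states))
  pair_grid <- pair_grid[pair_grid$i != pair_grid$j, ]
  grid_centers <- cbind(state_means[pair_grid$i], state_means[pair_grid$j])
  n_uniq <- nrow(unique(X))
  if (n_uniq <= k) {
    # degenerate TDP (e.g. idealized coordinates): unique points are clusters
    uX <- unique(X)
    cl <- match(paste(X[, 1], X[, 2]), paste(uX[, 1], uX[, 2]))
    centers <- uX
  } else {
    # seed k-means at the expected pair coordinates so sparse clusters
    # (rare transitions) are not absorbed by dense ones
    km <- tryCatch(
      stats::kmeans(X, centers = grid_centers, iter.max = 100),
      error = function(e) stats::kmeans(X, centers = k, nstart = 10,
                                        iter.max = 100))
    cl <- km$cluster
    centers <- km$centers
    gmm <- tryCatch({
      z <- mclust::unmap(cl, groups = seq_len(k))
      me <- mclust::me(data = X, modelName = "VVI", z = z)
      if (is.null(me$parameters) || any(!is.finite(me$z))) NULL else me
    }, error = function(e) NULL)
    if (!is.null(gmm)) {
      cl <- apply(gmm$z, 1, which.max)
      centers <- t(gmm$parameters$mean)
    }
    present <- sort(unique(cl))
    if (length(present) < k)
      warning("empty TDP cluster(s) merged: ", k - length(present),
              " of ", k)
    cl <- match(cl, present)
    centers <- centers[present, , drop = FALSE]
  }
  # map clusters to ordered state pairs, nearest grid point first
  pairs <- pair_grid
  grid <- grid_centers
  d <- as.matrix(stats::dist(rbind(centers, grid)))
  d <- d[seq_len(nrow(centers)), nrow(centers) + seq_len(nrow(grid)),
         drop = FALSE]
  assign_pair <- rep(NA_integer_, nrow(centers))
  taken <- rep(FALSE, nrow(grid))
  for (step in seq_len(min(nrow(centers), nrow(grid)))) {
    dd <- d
    dd[!is.na(assign_pair), ] <- Inf
    dd[, taken] <- Inf
    idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    assign_pair[idx[1]] <- idx[2]
    taken[idx[2]] <- TRUE
  }
  # leftover clusters (more clusters than pairs cannot happen; NA guards)
  events$cluster <- cl
  events$pair_before <- pairs$i[assign_pair[cl]]
  events$pair_after <- pairs$j[assign_pair[cl]]
  events
}

# Binned single-exponential decay fit to a dwell-time histogram; returns the
# decay constant (s^-1).
fit_exp_decay <- function(dwells, bins = 30) {
  h <- graphics::hist(dwells, breaks = bins, plot = FALSE)
  use <- h$counts > 0
  start <- c(A = max(h$counts), k = 1 / mean(dwells))
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ A * exp(-k * mids),
                      data = data.frame(counts = h$counts[use],
                                        mids = h$mids[use]),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  unname(stats::coef(fit)[["k"]])
}

#' Fit transition rates from clustered dwell times
#'
#' The default estimator is a censoring-aware exponential maximum-likelihood
#' fit under competing exits: for each ordered pair (i -> j) the rate is
#' `k_ij = n_ij / T_i`, where `n_ij` counts events assigned to that
#' cluster and `T_i` is the total time spent in state i (all dwells before
#' transitions out of i plus right-censored terminal dwells in i).  This is
#' the joint MLE of the exponential competing-risk model and is unbiased
#' under photobleaching truncation.  `method = "binned"` instead fits a
#' single-exponential decay to each cluster's dwell-time histogram and
#' reports its decay constant (the literal lifetime-fit route; note that
#' with several exits from state i this decay constant estimates the total
#' exit rate of i, and censored dwells are ignored).
#'
#' @param events Clustered events from [cluster_tdp()] (columns
#'   `pair_before`, `pair_after`; falls back to the segmentation states if
#'   clustering columns are absent).
#' @param censored Censored dwells from [extract_transitions()]; may be
#'   NULL (no censoring correction).
#' @param n_states Number of states.
#' @param method `"mle"` (default) or `"binned"`.
#' @param min_events Pairs with fewer events get `NA` rates (default 10).
#' @return Object of class `spt_rates`: `k` (n_states x n_states, s^-1,
#'   NA diagonal), `counts`, `state_time_s`, `method`, `n_censored`.
#' @export
fit_rates <- function(events, censored = NULL, n_states,
                      method = c("mle", "binned"), min_events = 10) {
  method <- match.arg(method)
  bi <- if ("pair_before" %in% names(events)) events$pair_before
        else events$state_before
  af <- if ("pair_after" %in% names(events)) events$pair_after
        else events$state_after
  ok <- !is.na(bi) & !is.na(af)
  bi <- bi[ok]; af <- af[ok]; dw <- events$dwell_before[ok]
  counts <- matrix(0L, n_states, n_states)
  for (e in seq_along(bi)) counts[bi[e], af[e]] <- counts[bi[e], af[e]] + 1L
  state_time <- vapply(seq_len(n_states), function(i) sum(dw[bi == i]),
                       numeric(1))
  n_censored <- 0L
  if (!is.null(censored) && nrow(censored)) {
    n_censored <- nrow(censored)
    for (i in seq_len(n_states))
      state_time[i] <- state_time[i] + sum(censored$dwell[censored$state == i])
  }
  k <- matrix(NA_real_, n_states, n_states)
  for (i in seq_len(n_states)) for (j in seq_len(n_states)) {
    if (i == j) next
    if (counts[i, j] < min_events) {
      message("pair ", i, "->", j, ": only ", counts[i, j],
              " events, rate omitted")
      next
    }
    k[i, j] <- if (method == "mle") counts[i, j] / state_time[i]
               else fit_exp_decay(dw[bi == i & af == j])
  }
  structure(list(k = k, counts = counts, state_time_s = state_time,
                 method = method, n_censored = n_censored),
            class = "spt_rates")
}

#' Transition rates implied by the HMM transition matrix
#'
#' Converts the fitted per-frame transition matrix A into continuous-time
#' rates.  Because A aggregates forward-backward posterior transition
#' counts, this estimator keeps its accuracy when state emissions overlap
#' (where hard Viterbi-path event counting undercounts transitions), and it
#' needs no censoring correction since it counts per-frame moves rather
#' than completed dwells.  `method = "log"` (default) takes the matrix
#' logarithm `Q = log(A)/t`, exact for a time-homogeneous chain;
#' `"linear"` uses the first-order `(A - I)/t`.
#'
#' @param model An `spt_hmm`.
#' @param method `"log"` or `"linear"`.
#' @return Matrix of rates (s^-1) with NA diagonal.
#' @export
hmm_implied_rates <- function(model, method = c("log", "linear")) {
  method <- match.arg(method)
  A <- model$transition_matrix
  t <- model$frame_interval
  K <- nrow(A)
  if (method == "linear" || K == 1) {
    k <- A / t
  } else {
    eg <- eigen(A)
    if (any(Re(eg$values) <= 0)) {
      k <- A / t  # principal log undefined; fall back
    } else {
      Q <- eg$vectors %*% diag(log(eg$values), K) %*% solve(eg$vectors)
      k <- pmax(Re(Q), 0) / t
    }
  }
  diag(k) <- NA_real_
  k
}

#' Transition-state-theory activation energy of a rate constant
#'
#' `Ea = -R T log(h k / (kB T))` in kJ/mol: the Eyring barrier height for a
#' first-order rate constant `k` at temperature `T`, with unit transmission.
#'
#' @param k_ij Rate constant(s), s^-1; must be > 0.
#' @param T Temperature (K), default 298.
#' @param constants Physical constants, see [spt_constants].
#' @return Activation energy in kJ/mol (vectorized; NA in gives NA out).
#' @export
energy_barrier <- function(k_ij, T = spt_constants$T,
                           constants = spt_constants) {
  if (any(k_ij <= 0, na.rm = TRUE)) stop("rates must be > 0")
  -constants$R * T * log(constants$h * k_ij / (constants$kB * T)) / 1000
}

#' Free-energy difference between two states from forward/backward rates
#'
#' `dG = -R T log(k_ij / k_ji)` in kJ/mol; negative when the j -> i barrier
#' exceeds the i -> j barrier, i.e. state j lies below state i.
#'
#' @param k_ij,k_ji Forward and backward rate constants (s^-1), both > 0.
#' @param T Temperature (K).
#' @param constants Physical constants.
#' @return Free-energy difference in kJ/mol.
#' @export
free_energy_difference <- function(k_ij, k_ji, T = spt_constants$T,
                                   constants = spt_constants) {
  if (any(c(k_ij, k_ji) <= 0, na.rm = TRUE))
    stop("both rates must be > 0")
  -constants$R * T * log(k_ij / k_ji) / 1000
}

#' Assemble the quantitative state diagram
#'
#' Combines occupancies, the fitted rate matrix, activation energies and
#' pairwise free-energy differences into one kinetic model, and reports
#' consistency checks: the stationary distribution of the rate matrix
#' against the measured occupancies, the round-trip free-energy sum over
#' the 3-cycle (zero iff detailed balance holds), and the elementwise ratio
#' of the diagram's rates to a second rate estimate when one is supplied
#' (e.g. dwell-fit vs posterior-count rates).
#'
#' @param occupancies Per-state occupancy fractions.
#' @param rates An `spt_rates` object or plain rate matrix (s^-1).
#' @param T Temperature (K).
#' @param cross_rates Optional second rate matrix for the sanity report.
#' @return Object of class `spt_kinetic_model` with elements `occupancies`,
#'   `k`, `Ea`, `dG`, `constants`, `T`, `stationary_from_k`,
#'   `cycle_dG` (3-state models), `rate_ratio`, `missing_rates`.
#' @export
build_state_diagram <- function(occupancies, rates, T = spt_constants$T,
                                cross_rates = NULL) {
  k <- if (inherits(rates, "spt_rates")) rates$k else as.matrix(rates)
  K <- nrow(k)
  diag(k) <- NA_real_
  Ea <- matrix(NA_real_, K, K)
  pos <- which(!is.na(k) & k > 0)
  Ea[pos] <- energy_barrier(k[pos], T)
  dG <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i != j && isTRUE(k[i, j] > 0) && isTRUE(k[j, i] > 0))
      dG[i, j] <- free_energy_difference(k[i, j], k[j, i], T)
  }
  missing <- sum(is.na(k)) - K
  if (missing > 0)
    warning(missing, " transition rate(s) missing from the diagram")
  stat <- if (all(!is.na(k[row(k) != col(k)]))) {
    km <- k; km[is.na(km)] <- 0
    stationary_distribution(km)
  } else NULL
  cycle <- if (K == 3 && !any(is.na(c(dG[1, 2], dG[2, 3], dG[3, 1]))))
    dG[1, 2] + dG[2, 3] + dG[3, 1] else NA_real_
  ratio <- if (!is.null(cross_rates)) {
    cr <- if (inherits(cross_rates, "spt_rates")) cross_rates$k
          else as.matrix(cross_rates)
    k / cr
  } else NULL
  structure(list(occupancies = occupancies, k = k, Ea = Ea, dG = dG,
                 constants = spt_constants, T = T,
                 stationary_from_k = stat, cycle_dG = cycle,
                 rate_ratio = ratio, missing_rates = missing),
            class = "spt_kinetic_model")
}
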