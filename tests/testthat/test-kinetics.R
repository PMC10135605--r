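test_that("transition extraction counts adjacent segment pairs", {
  const <- make_segmented(rep(1L, 20))
  tr0 <- extract_transitions(list(const))
  expect_equal(nrow(tr0$events), 0L)
  expect_equal(nrow(tr0$censored), 1L)

  two <- make_segmented(c(rep(1L, 10), rep(2L, 5)))
  tr <- extract_transitions(list(two))
  expect_equal(nrow(tr$events), 1L)
  expect_equal(tr$events$dwell_before, 10 * 0.081)
  expect_equal(tr$events$state_before, 1L)
  expect_equal(tr$events$state_after, 2L)

  set.seed(71)
  segs <- lapply(1:30, function(p)
    make_segmented(sample(1:3, 40, replace = TRUE), particle_id = p))
  trs <- extract_transitions(segs)
  n_segments <- sum(vapply(segs, function(s) nrow(s$segments), integer(1)))
  expect_equal(nrow(trs$events), n_segments - 30L)  # (segments - 1) per trace
  # no diagonal events by construction
  expect_true(all(trs$events$state_before != trs$events$state_after))
})

test_that("TDP clustering assigns events at exact pair coordinates", {
  means <- c(0.03, 0.09, 0.2)
  pairs <- expand.grid(i = 1:3, j = 1:3)
  pairs <- pairs[pairs$i != pairs$j, ]
  ev <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k)
    data.frame(particle_id = 1, state_before = pairs$i[k],
               state_after = pairs$j[k],
               mean_step_before = means[pairs$i[k]],
               mean_step_after = means[pairs$j[k]],
               dwell_before = 0.5)[rep(1, 20), ]))
  cl <- cluster_tdp(ev, 3, state_means = means)
  expect_true(all(cl$pair_before == cl$state_before))
  expect_true(all(cl$pair_after == cl$state_after))
  expect_error(cluster_tdp(ev[1:3, ], 3, state_means = means), "at least")
})

test_that("TDP clustering separates simulated transitions by pair", {
  traces <- simulate_hmm_steps(800, mean_steps = c(0.03, 0.09, 0.3),
                               shape = 30, seed = 72)
  fit <- fit_hmm(traces, 3, seed = 1)
  seg <- segment_traces(fit, traces)
  tr <- extract_transitions(seg)
  ev <- cluster_tdp(tr$events, 3, state_means = fit$emissions$mean_step)
  agree <- mean(ev$pair_before == ev$state_before &
                ev$pair_after == ev$state_after)
  expect_gte(agree, 0.95)
})

test_that("dwell-time MLE equals closed forms and respects censoring", {
  ev1 <- data.frame(particle_id = 1, state_before = 1, state_after = 2,
                    mean_step_before = 0.03, mean_step_after = 0.2,
                    dwell_before = rep(1, 50))
  r1 <- fit_rates(ev1, NULL, 2)
  expect_equal(r1$k[1, 2], 1)            # uncensored MLE = 1/mean dwell
  expect_true(is.na(r1$k[2, 1]))

  set.seed(73)
  dw <- stats::rexp(1e4, 2.48)
  ev2 <- ev1[rep(1, 1e4), ]
  ev2$dwell_before <- dw
  r2 <- fit_rates(ev2, NULL, 2)
  expect_equal(r2$k[1, 2], 1 / mean(dw), tolerance = 1e-12)
  expect_lt(abs(r2$k[1, 2] - 2.48), 3 * 2.48 / sqrt(1e4))

  # ignoring censoring overestimates the rate
  true_dw <- stats::rexp(4000, 1)
  cens_at <- stats::rexp(4000, 1)
  obs <- pmin(true_dw, cens_at)
  is_event <- true_dw <= cens_at
  ev3 <- data.frame(particle_id = 1, state_before = 1, state_after = 2,
                    mean_step_before = 0.03, mean_step_after = 0.2,
                    dwell_before = obs[is_event])
  cen <- data.frame(particle_id = 1, state = 1, dwell = obs[!is_event])
  k_aware <- fit_rates(ev3, cen, 2)$k[1, 2]
  k_naive <- fit_rates(ev3, NULL, 2)$k[1, 2]
  expect_gt(k_naive, k_aware)
  expect_lt(abs(k_aware - 1), 3 / sqrt(sum(is_event)))

  # binned single-exponential decay route agrees on clean dwells
  k_binned <- fit_rates(ev2, NULL, 2, method = "binned")$k[1, 2]
  expect_lt(abs(k_binned - 2.48) / 2.48, 0.15)

  expect_message(fit_rates(ev1[1:5, ], NULL, 2), "rate omitted")
})

test_that("transition-state theory energies match analytic anchors", {
  expect_lt(abs(energy_barrier(2.48, 298) - 70.7), 0.05)
  expect_lt(abs(energy_barrier(0.27, 298) - 76.2), 0.05)
  k_attempt <- spt_constants$kB * 298 / spt_constants$h
  expect_equal(energy_barrier(k_attempt, 298), 0, tolerance = 1e-9)
  expect_error(energy_barrier(0), "> 0")
  # strictly decreasing in k at fixed T
  ks <- c(0.1, 0.27, 1, 2.48, 10)
  expect_true(all(diff(energy_barrier(ks, 298)) < 0))
})

test_that("free-energy differences are antisymmetric and zero at symmetry", {
  expect_equal(free_energy_difference(1.3, 1.3), 0)
  expect_equal(free_energy_difference(2.48, 0.27),
               -free_energy_difference(0.27, 2.48))
  expect_lt(abs(free_energy_difference(2.48, 0.27, 298) - (-5.494)), 0.01)
  expect_error(free_energy_difference(0, 1), "> 0")
})

test_that("HMM-implied rates invert the discretized chain exactly", {
  Q <- default_rate_matrix()
  diag(Q) <- -rowSums(Q)
  A <- sptstates:::matrix_exp(Q * 0.081)
  model <- make_hmm(c(0.03, 0.09, 0.2), A = A)
  k <- hmm_implied_rates(model)
  off <- row(Q) != col(Q)
  expect_lt(max(abs(k[off] - default_rate_matrix()[off])), 1e-8)
  k_lin <- hmm_implied_rates(model, "linear")
  expect_gt(max(abs(k_lin[off] - default_rate_matrix()[off])), 1e-4)
})

test_that("the assembled state diagram is thermodynamically consistent", {
  k2 <- matrix(c(NA, 0.7, 0.7, NA), 2, 2)
  d2 <- build_state_diagram(c(0.5, 0.5), k2)
  expect_equal(d2$dG[1, 2], 0)
  expect_equal(d2$stationary_from_k, c(0.5, 0.5), tolerance = 1e-12)

  # detailed-balance 3-state rates: pi = (0.2, 0.5, 0.3)
  k3 <- matrix(c(0, 0.5, 0.3, 0.2, 0, 0.3, 0.2, 0.5, 0), 3, 3, byrow = TRUE)
  d3 <- build_state_diagram(c(0.2, 0.5, 0.3), k3)
  expect_equal(unname(d3$stationary_from_k), c(0.2, 0.5, 0.3),
               tolerance = 1e-10)
  expect_equal(d3$cycle_dG, 0, tolerance = 1e-10)
  expect_equal(d3$dG[1, 2], -d3$dG[2, 1])
  # dG from rates equals dG from occupancy ratios under detailed balance
  expect_equal(d3$dG[1, 2],
               -spt_constants$R * 298 * log(0.5 / 0.2) / 1000,
               tolerance = 1e-10)

  km <- k3; km[1, 3] <- NA
  expect_warning(dm <- build_state_diagram(c(0.2, 0.5, 0.3), km), "missing")
  expect_true(is.na(dm$Ea[1, 3]))
})
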