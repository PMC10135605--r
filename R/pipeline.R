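# End-to-end orchestration: simulation (or user-supplied localizations /
# trajectories / movies) -> linking -> diffusion coefficients -> HMM state
# selection -> Viterbi segmentation -> TDP kinetics -> state diagram.
# Stages communicate through files so users can enter the chain at any
# point with their own data.

#' Run configuration for the SPT analysis pipeline
#'
#' @param mode Input mode: `"simulate"` (generate synthetic data),
#'   `"trajectories"`, `"localizations"` or `"movie"` (each reads `input`).
#' @param input Path to the input file for non-simulate modes.
#' @param seed Integer seed; mandatory, drives every stochastic stage.
#' @param sim [simulation_config()] for simulate mode (its own seed is
#'   overridden by `seed`).
#' @param frame_interval Frame interval (s) for non-simulate inputs.
#' @param search_range_um,memory Linking parameters (see
#'   [link_trajectories()]).
#' @param min_steps Minimum steps per trace for the HMM (default 10).
#' @param candidates State counts scanned by BIC (default 1:4).
#' @param temperature_K Temperature for the energy calculations.
#' @param emccd An `spt_emccd` for movie mode (calibrated from the movie's
#'   metadata when omitted).
#' @return List of class `spt_run_config`.
#' @export
run_config <- function(mode = c("simulate", "trajectories", "localizations",
                                "movie"),
                       input = NULL, seed = 1L, sim = simulation_config(),
                       frame_interval = 0.081, search_range_um = 0.8,
                       memory = 1L, min_steps = 10L, candidates = 1:4,
                       temperature_K = spt_constants$T, emccd = NULL) {
  mode <- match.arg(mode)
  if (mode != "simulate" && is.null(input))
    stop("mode '", mode, "' requires an input path")
  structure(list(mode = mode, input = input, seed = as.integer(seed),
                 sim = sim, frame_interval = frame_interval,
                 search_range_um = search_range_um, memory = memory,
                 min_steps = min_steps, candidates = candidates,
                 temperature_K = temperature_K, emccd = emccd),
            class = "spt_run_config")
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the [run_config()] arguments; the `sim` block holds
#' [simulation_config()] fields (`rate_matrix` as a nested array).
#'
#' @param path JSON file path.
#' @return `spt_run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$seed)) stop("config JSON must set a seed")
  sim <- if (!is.null(j$sim)) {
    s <- j$sim
    do.call(simulation_config, c(
      s[setdiff(names(s), "rate_matrix")],
      if (!is.null(s$rate_matrix))
        list(rate_matrix = matrix(unlist(s$rate_matrix),
                                  nrow = s$n_states, byrow = TRUE))))
  } else simulation_config()
  args <- j[setdiff(names(j), "sim")]
  do.call(run_config, c(args, list(sim = sim)))
}

serialize_hmm <- function(model) {
  list(n_states = model$n_states,
       initial_probs = model$initial_probs,
       transition_matrix = apply(model$transition_matrix, 1, as.numeric,
                                 simplify = FALSE),
       emissions = model$emissions,
       log_likelihood = model$log_likelihood,
       n_params = model$n_params, bic = model$bic, n_obs = model$n_obs,
       n_traces = model$n_traces, frame_interval = model$frame_interval,
       converged = model$converged)
}

#' Run the full SPT analysis pipeline
#'
#' Deterministic given the configured seed.  Every stage's outputs are
#' written under `outdir`: trajectory and segmentation CSVs, diffusion
#' table, HMM model JSON with the BIC table, kinetic model JSON, and a
#' top-level `report.json`.
#'
#' @param config An [run_config()] (or path to a config JSON).
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the report and fitted objects
#'   (`trajectories`, `steps`, `diffusion`, `selection`, `segmented`,
#'   `transitions`, `rates`, `diagram`, `report`).
#' @export
run_spt <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "spt_run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  frame_interval <- config$frame_interval

  traj <- switch(config$mode,
    simulate = {
      cfg <- config$sim
      cfg$seed <- config$seed
      frame_interval <- cfg$frame_interval
      simulate_trajectories(cfg)
    },
    trajectories = read_trajectories(config$input),
    localizations = {
      loc <- utils::read.csv(config$input)
      link_trajectories(loc, config$search_range_um, config$memory)
    },
    movie = {
      movie <- read_movie_tiff(config$input)
      md <- movie$metadata
      emccd <- if (!is.null(config$emccd)) config$emccd
               else emccd_model(md$offset, md$gain, md$read_noise)
      if (!is.null(md$frame_interval_s)) frame_interval <- md$frame_interval_s
      loc <- localize_movie(movie, emccd,
                            pixel_size_um = md$pixel_size_um)
      link_trajectories(loc, config$search_range_um, config$memory)
    })
  write_trajectories(traj, file.path(outdir, "trajectories.csv"))

  steps <- to_steps(traj, frame_interval)
  n_all <- length(steps)
  steps <- Filter(function(s) length(s$r) >= config$min_steps, steps)
  if (length(steps) < 10) stop("fewer than 10 traces with >= ",
                               config$min_steps, " steps")

  diffusion <- estimate_diffusion(steps)
  utils::write.csv(diffusion, file.path(outdir, "diffusion.csv"),
                   row.names = FALSE)

  sel <- select_n_states(steps, candidates = config$candidates,
                         seed = config$seed)
  model <- sel$best
  jsonlite::write_json(list(model = serialize_hmm(model),
                            bic_table = sel$bic_table),
                       file.path(outdir, "hmm_model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  segmented <- segment_traces(model, steps)
  seg_rows <- do.call(rbind, lapply(segmented, function(s)
    data.frame(particle_id = s$particle_id, step = seq_along(s$states),
               r_um = s$r, state = s$states,
               idealized_r_um = model$emissions$mean_step[s$states])))
  utils::write.csv(seg_rows, file.path(outdir, "segmentation.csv"),
                   row.names = FALSE)
  occ <- occupancy(segmented, model$n_states)

  trans <- extract_transitions(segmented)
  rates_dwell <- diagram <- NULL
  rates_hmm <- if (model$n_states >= 2) hmm_implied_rates(model) else NULL
  if (model$n_states >= 2 &&
      nrow(trans$events) >= model$n_states * (model$n_states - 1)) {
    ev <- cluster_tdp(trans$events, model$n_states,
                      state_means = model$emissions$mean_step,
                      seed = config$seed)
    utils::write.csv(ev, file.path(outdir, "tdp_events.csv"),
                     row.names = FALSE)
    rates_dwell <- fit_rates(ev, trans$censored, model$n_states)
    # primary rates: posterior-count route (robust to emission overlap);
    # the TDP dwell-fit route is reported and cross-checked alongside
    diagram <- build_state_diagram(occ, rates_hmm,
                                   T = config$temperature_K,
                                   cross_rates = rates_dwell)
    jsonlite::write_json(
      list(occupancies = occ,
           k_per_s = apply(diagram$k, 1, as.numeric, simplify = FALSE),
           k_dwell_per_s = apply(rates_dwell$k, 1, as.numeric,
                                 simplify = FALSE),
           event_counts = apply(rates_dwell$counts, 1, as.numeric,
                                simplify = FALSE),
           Ea_kJ_mol = apply(diagram$Ea, 1, as.numeric, simplify = FALSE),
           dG_kJ_mol = apply(diagram$dG, 1, as.numeric, simplify = FALSE),
           temperature_K = config$temperature_K,
           cycle_dG_kJ_mol = diagram$cycle_dG,
           rate_method = "hmm_posterior_counts",
           dwell_method = rates_dwell$method),
      file.path(outdir, "kinetic_model.json"), auto_unbox = TRUE,
      digits = NA)
  }

  report <- list(
    mode = config$mode, seed = config$seed,
    frame_interval_s = frame_interval,
    n_traces_input = n_all, n_traces_used = length(steps),
    n_steps_total = model$n_obs,
    bic_table = sel$bic_table, n_states_selected = sel$n_states,
    state_mean_steps_um = model$emissions$mean_step,
    occupancies = as.list(occ),
    mean_D_um2_s = mean(diffusion$D_um2_s),
    mean_log10D = mean(diffusion$log10D[is.finite(diffusion$log10D)]),
    rates_per_s = if (!is.null(diagram))
      apply(diagram$k, 1, as.numeric, simplify = FALSE),
    rates_dwell_per_s = if (!is.null(rates_dwell))
      apply(rates_dwell$k, 1, as.numeric, simplify = FALSE),
    Ea_kJ_mol = if (!is.null(diagram))
      apply(diagram$Ea, 1, as.numeric, simplify = FALSE)
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(trajectories = traj, steps = steps, diffusion = diffusion,
                 selection = sel, segmented = segmented,
                 transitions = trans, rates_dwell = rates_dwell,
                 rates = if (!is.null(diagram)) diagram$k else NULL,
                 diagram = diagram, report = report))
}
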