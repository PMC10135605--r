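# sptstates

Mobility states and transition kinetics from single-particle tracking (SPT).

## The problem

Interfacial enzymes such as lipases work while diffusing on a substrate
surface, and their surface mobility correlates with catalytic activity.
TIRF microscopy can record thousands of single fluorescently labeled
enzymes in parallel, but a trajectory is not a number: each molecule
switches between mobility states — an arrested, essentially immobile state
whose apparent motion is pure localization error, a slow state, and a fast
diffusive state — and the biology lives in the states' abundances, the
rates of switching between them, and the energy barriers those rates imply.

`sptstates` turns trajectories (or synthetic TIRF-like movies) into that
quantitative picture:

1. **Diffusion coefficients.** For 2D Brownian motion the step length `r`
   at lag `t` follows `p(r, t, D) = r/(2Dt) · exp(−r²/4Dt)`; the
   per-trajectory maximum-likelihood estimate is the closed form
   `D̂ = Σ rᵢ² / (4 n t)`, used without binning.
2. **Hidden Markov modeling.** Step-length traces are modeled by an HMM
   with per-state gamma emissions, fitted by Baum–Welch jointly across all
   traces (forward–backward in compiled code); the number of states is
   chosen by BIC over 1–4 states and traces are segmented with Viterbi.
3. **Transition kinetics.** State changes are collected into transition
   density plots (TDPs), clustered by k-means + a 2D Gaussian mixture, and
   dwell times fitted by censoring-aware exponential maximum likelihood
   (photobleaching truncates dwells); a posterior-count rate estimate from
   the HMM transition matrix is reported alongside and used as the primary
   rate matrix because it stays unbiased when state emissions overlap.
4. **Transition-state theory.** Each rate maps to an activation energy
   `Eₐ = −RT ln(h·k/(k_B·T))` and each state pair to a free-energy
   difference `ΔG = −RT ln(k_ij/k_ji)` (kJ/mol, default T = 298 K).
5. **Synthetic data.** A simulator with known ground truth generates
   multi-state switching Brownian trajectories (continuous-time Markov
   switching sampled at 81 ms frames, Gaussian localization noise,
   exponential photobleaching) and can render them into 16-bit TIRF-like
   movies through a pixel-integrated Gaussian PSF and an EMCCD noise model
   (offset, gain, read noise). The imaging module inverts that model:
   mean–variance EMCCD calibration, spot detection, sub-pixel PSF fitting,
   and simulation-based localization-error estimation.

## Worked example

```r
library(sptstates)

## simulate a three-state switching-diffusion experiment (500 tracks)
cfg <- simulation_config(n_particles = 500, seed = 42)
traj <- simulate_trajectories(cfg)

## step-length traces and per-trajectory diffusion coefficients
steps <- Filter(function(s) length(s$r) >= 10,
                to_steps(traj, cfg$frame_interval))
diffusion <- estimate_diffusion(steps)
round(mean(diffusion$D_um2_s), 4)
#> [1] 0.0256

## fit the 3-state gamma-emission HMM and segment the traces
fit <- fit_hmm(steps, n_states = 3, seed = 1)
fit$emissions
#>   state    shape       scale  mean_step
#> 1     1 2.913423 0.009141565 0.02663324
#> 2     2 3.270335 0.017569789 0.05745910
#> 3     3 3.203181 0.050307980 0.16114558

seg <- segment_traces(fit, steps)
round(occupancy(seg), 3)
#> state1 state2 state3
#>  0.275  0.556  0.169

## transition kinetics and transition-state-theory energies
trans <- extract_transitions(seg)
ev    <- cluster_tdp(trans$events, 3, state_means = fit$emissions$mean_step)
rates <- fit_rates(ev, trans$censored, 3)
diagram <- build_state_diagram(occupancy(seg), hmm_implied_rates(fit),
                               cross_rates = rates)
round(diagram$k, 2)    # rates, s^-1 (row -> column)
#>      [,1] [,2] [,3]
#> [1,]   NA 0.86 0.25
#> [2,] 0.51   NA 0.32
#> [3,] 0.29 1.13   NA
round(diagram$Ea, 1)   # activation energies, kJ/mol
#>      [,1] [,2] [,3]
#> [1,]   NA 73.4 76.4
#> [2,] 74.6   NA 75.8
#> [3,] 76.1 72.7   NA
```

The state mean steps (0.027, 0.057, 0.161 µm) reproduce the immobile /
slow / fast structure of the generator (localization noise alone gives a
mean step of `σ_loc·√π ≈ 0.027 µm`); the recovered rates sit within a few
percent of the generator's 0.27–1.2 s⁻¹ ground truth, and the energies
fall in the low-70s kJ/mol range typical for second-scale interfacial
switching. `ΔG` (in `diagram$dG`) shows the slow state as the free-energy
minimum, matching its dominant occupancy.

The same analysis runs end to end with `run_spt()` (modes `simulate`,
`trajectories`, `localizations`, `movie`), which writes trajectory,
diffusion, segmentation and kinetic-model files plus a JSON report; a thin
command-line wrapper lives in `inst/scripts/spt-pipeline.R`.

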