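Package: sptstates
Title: Mobility States and Transition Kinetics from Single-Particle Tracking
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of surface diffusion recorded by
    single-particle tracking (SPT) of fluorescently labeled enzymes on
    substrate surfaces, from TIRF-like image stacks or trajectory tables to
    diffusion coefficients, hidden-Markov mobility states, transition rates
    and transition-state-theory energy barriers.  Includes a synthetic-data
    generator for multi-state switching Brownian motion with an
    EMCCD/point-spread-function imaging model, nearest-neighbor trajectory
    linking with gap memory, maximum-likelihood diffusion-coefficient
    estimation from step lengths, Baum-Welch fitting of hidden Markov models
    with gamma step-length emissions and BIC model selection, Viterbi
    segmentation, transition-density-plot clustering, censoring-aware
    exponential dwell-time rate estimation, and Eyring/transition-state-theory
    activation and free-energy calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    mclust,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
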