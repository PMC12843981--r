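Package: nanotrap
Title: Analysis of Nanoaperture Optical Tweezer Single-Protein Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing transmitted-intensity time traces from
    nanoaperture optical tweezer (NOT) single-protein trapping experiments.
    Provides trapping-event detection, Welch power-spectral-density
    estimation with Lorentzian corner-frequency fits, zero-power
    extrapolation of the corner frequency to quantify electrostatic
    protein-surface interactions, derivative-threshold detection of
    two-state conformational transitions with occupancy and dwell-time
    statistics, and reconstruction of Gibbs free-energy landscapes by
    dithered density estimation, Richardson-Lucy deconvolution and
    Boltzmann inversion, including quadratic stability analysis of the
    free-energy difference versus temperature. A seeded synthetic-trace
    generator with exact Ornstein-Uhlenbeck discretisation and two-state
    Markov switching supplies ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
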