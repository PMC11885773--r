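Package: mtfold
Title: Simulation and Analysis of Single-Protein Folding Under Force in
    Magnetic Tweezers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for single-molecule magnetic tweezers protein-folding
    experiments. Builds a one-dimensional force-tilted free-energy landscape
    (Morse-like folded well, Gaussian barrier, worm-like-chain entropic tail),
    generates overdamped Langevin trajectories under constant-force,
    force-ramp and force-jump protocols, extracts states, dwell times, rates,
    step sizes and folding probabilities from trajectories, fits
    force-dependent rate laws (Bell, Dudko-Hummer-Szabo, first-passage
    freely-jointed-chain refolding), fits force-ramp rupture-force
    distributions by maximum likelihood, and provides instrument
    force-calibration utilities (exponential magnet law, tape-head law,
    equipartition force, step-size calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
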