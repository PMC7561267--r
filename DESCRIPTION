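Package: dgfpace
Title: Delayed Global Feedback in Periodically Paced Excitable Media
Version: 0.1.0
Authors@R:
    person("dgfpace", "developers", email = "dgfpace@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of spatiotemporal period-2 (alternans)
    patterns in periodically paced one-dimensional excitable media subject to
    delayed global feedback (DGF). Provides a diffusively coupled
    FitzHugh-Nagumo lattice with a feedback-modulated pacing pulse, a coupled
    map lattice (CML) with Gaussian spatial coupling and a nonlinear DGF term,
    analytic linear-stability machinery for the uniform period-1 and
    concordant period-2 states (Fourier-mode eigenvalue spectra and phase
    boundary curves), a pattern classification pipeline (uniform P1,
    concordant P2, discordant P2, node and domain-size detection), and
    reproducible experiment drivers for phase diagrams, domain-size
    histograms and discordant-fraction curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
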