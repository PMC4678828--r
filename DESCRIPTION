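Package: ssbkin
Title: Single-Molecule Multi-Process Analysis of SSB Binding Kinetics to ssDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation and kinetic analysis of single-stranded-DNA
    binding protein (SSB) association dynamics observed by combined
    single-molecule FRET, protein-induced fluorescence enhancement (PIFE) and
    acceptor self-quenching. Provides a continuous-time Markov simulator of
    monomer-by-monomer binding that renders noisy two-channel camera
    trajectories, a threshold classifier mapping frames to photophysical
    states, dwell-time exponential inference with branching-corrected
    transition rates and bimolecular fits, and ensemble binding-isotherm
    models (Hill, sequential two-site, donor-quench FRET, RatioA and Forster
    distance conversion), with tidy tibble interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
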