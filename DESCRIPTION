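Package: nfkbtherm
Title: Temperature-Dependent Modelling and Analysis of NF-kB Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the NF-kB / IkB / IKK negative-feedback oscillator with
    temperature-dependent reaction rates (reaction-limited and diffusion-limited
    linear scaling laws), and analyses the resulting dynamics: power-spectral
    period extraction, Hopf-onset location, period-versus-temperature sweeps,
    Hill-function downstream gene production and its temperature crossover,
    entrainment by oscillating temperature (rotation numbers, Devil's
    staircases, plateau widths, multistability) and the transition to chaos
    diagnosed by twin-trajectory divergence and Lyapunov exponents. Includes a
    generator of synthetic single-cell nuclear/cytoplasmic intensity-ratio
    traces and the smoothing/detrending/period-extraction pipeline used to
    analyse them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
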