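Package: photoKv
Title: Voltage-Gated Potassium Conductance Analysis and Photoreceptor
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterization of voltage-gated potassium conductances from
    whole-cell patch-clamp recordings and a Hodgkin-Huxley-type model of an
    insect (cockroach) photoreceptor. Provides closed-form gating mathematics
    (Boltzmann steady states, bell-function time constants, Nernst
    electrochemistry), a stiff-capable simulator for voltage-clamp and
    current-clamp (light-response) protocols including the two-prepulse
    subtraction protocol that isolates the transient A-type current, the
    full curve-fitting pipeline (Boltzmann activation/inactivation,
    exponential and pulse-function kinetics, bell time-constant, tail-current
    reversal potentials, Nernst slopes, dose-response logistics, test-pulse
    passive properties), and seeded synthetic-data generators so every stage
    is testable by parameter recovery without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
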