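Package: lymphnet
Title: Lumped-Parameter Simulation of Pumping in Branched Lymphatic
    Vessel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates lymph transport through converging bifurcating
    networks of actively contracting, valved lymphangions using a
    lumped-parameter (0D) model. Each lymphangion obeys a nonlinear
    passive pressure-diameter tube law with diameter- and time-dependent
    active muscle tension; intraluminal valves are modelled as smooth
    sigmoidal resistances that close at a slightly negative pressure
    difference and prolapse (fail open) at strongly negative pressures.
    The package builds symmetric bifurcating trees, assigns contraction
    wave schedules with intra-vessel and junction time delays, integrates
    the stiff diameter ODEs to a periodic state, and provides parameter
    sweep drivers for pump-function curves and coordination/pressure
    studies, with tidy tibble outputs and ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
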