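Package: photoclock
Title: Circadian-Clock-Controlled Photosynthesis Modelling in Tomato
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A kinetic model of the tomato circadian oscillator coupled to
    photosynthetic gene expression and gas-exchange output. Implements a
    29-variable ordinary differential equation system (a compact six-gene
    clock with protein complexes and a light-sensitive protein, plus four
    photosynthetic gene pairs), fixed-step classical Runge-Kutta simulation
    under light-dark and constant-light protocols with a light-intensity
    input function, rhythm analysis by harmonic fitting, maximum-entropy
    spectral analysis and the Enright periodogram, simulated-annealing
    parameter estimation against expression, period and phase targets,
    robustness, sensitivity and Hopf bifurcation analysis, a Hill-kinetics
    model of net photosynthesis, stomatal conductance, intercellular CO2
    and transpiration, and a synthetic-data generator emulating RT-qPCR
    time courses and diurnal gas-exchange measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
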