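Package: osnet
Title: Orientation Selectivity in Inhibition-Dominated Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the emergence of orientation selectivity in
    random recurrent networks of integrate-and-fire neurons without
    feature-specific connectivity. Provides a clock-driven simulator for
    networks of perfect (PIF) and leaky (LIF) integrate-and-fire neurons
    with delta synapses, transmission delays and orientation-tuned Poisson
    drive; an analytical firing-rate theory that predicts every neuron's
    stationary rate (linear solution, rectified fixed point, and the
    Siegert first-passage transfer-function fixed point); and a toolkit of
    tuning statistics (OSI, preferred orientation, von Mises fits, tuning
    width, F0/F2 components, sharpening coefficient, CV of inter-spike
    intervals, free-membrane-potential reconstruction) used to
    characterise selectivity and its contrast invariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
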