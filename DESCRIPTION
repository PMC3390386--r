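Package: olivenet
Title: Clustered Gap-Junction Network Model of Inferior Olive Subthreshold Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of electrically coupled two-conductance
    (leak plus low-threshold T-type calcium) model neurons arranged in
    conductance-similar clusters, as found in the inferior olive. Provides a
    constrained pseudo-random network generator (cluster sizes, intra-cluster
    degree, per-neuron connection limits, coupling coefficients calibrated to
    the 2-20% experimental range), a coupled-ODE simulator with mid-run
    modulation of inter-cluster gap-junction strengths, and analysis tools for
    subthreshold oscillations: peak detection, stability, FFT and short-time
    FFT frequency estimation, phase maps, peak-time cross-correlograms and
    wave-order statistics. Includes an "average neuron" frequency predictor
    for coupled ensembles and protocol drivers for staged-coupling,
    modulation, ensemble and phase experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
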