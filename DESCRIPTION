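Package: rdconnectome
Title: Reaction-Diffusion Dynamics on Weighted Directed Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of reaction-diffusion dynamics on weighted
    directed networks, aimed at connectome-scale models of signal propagation and
    demyelinating lesions. Implements Gierer-Meinhardt, Mimura-Murray, Gray-Scott
    and Wilson-Cowan kinetics coupled through a mass-conserving graph diffusion
    operator, with time-varying connection weights, Ornstein-Uhlenbeck coupling
    noise, and distance-relay expansion of edges. Downstream analysis covers
    cross-correlation and co-activation similarity matrices, the Kuramoto order
    parameter, spectral and Markov clustering, Jaccard comparison of clusterings,
    parameter sweeps, linear stability and bifurcation analysis of the
    Gierer-Meinhardt fixed point, surrogate network generators and a bilateral
    mechanosensory fixture connectome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
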