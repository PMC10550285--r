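Package: thetanet
Title: Spiking Network Model of Extrinsic and Intrinsic Hippocampal Theta Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a CA3-dentate gyrus spiking network (Izhikevich neurons,
    conductance-based synapses with transmission delay, short-term synaptic
    depression and facilitation, and a hard-wired CA3-DG-CA3 feedback loop)
    that generates movement-driven (extrinsic) and connectivity-driven
    (intrinsic) theta sequences of place cells in a two-dimensional arena.
    Includes the full analysis stack for theta-timescale spike correlations:
    theta-phase assignment, circular-linear regression of phase precession,
    cross-correlograms with 4-12 Hz correlation-lag phases, extrinsicity and
    intrinsicity of place-field pairs, theta-compression regression, spike-time
    gradient maps, and a tempotron readout that detects intrinsic sequences as
    direction-invariant temporal landmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
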