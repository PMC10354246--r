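Package: sspslam
Title: Spatial Semantic Pointer SLAM in Spiking-Neural-Network Style
Version: 0.1.0
Authors@R: person("sspslam", "developers", role = c("aut", "cre"),
    email = "devs@example.org")
Description: A biologically motivated simultaneous-localization-and-mapping
    (SLAM) toolkit in which positions, landmarks and semantic features are
    represented as high-dimensional vectors (Spatial Semantic Pointers). Path
    integration is carried out by velocity-controlled oscillators with an
    attractor-stabilised unit circle, an environment map is learned online in
    a heteroassociative memory via the PES and Voja rules, and loop closure
    corrects dead-reckoning drift. Includes a holographic-reduced-
    representation algebra, a minimal Neural Engineering Framework runtime
    (LIF tuning curves, least-squares decoders, synaptic filtering, dynamics
    transform), kernel-density probability readout with MAP decoding,
    synthetic environment and band-limited trajectory generators, metrics,
    and a command-line interface. Everything runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
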