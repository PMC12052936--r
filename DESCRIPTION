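Package: acidfront
Title: Traveling Fronts and Interface Instabilities in an Acid-Mediated
    Tumor Invasion Model with Allee Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the modified Gatenby-Gawlinski reaction-diffusion
    model of acid-mediated tumor invasion with an Allee effect in the tumor
    growth law.  Constructs bistable one-dimensional invasion fronts both in
    the singular limit (geometric singular perturbation theory: layer fronts,
    slow Hamiltonian orbits, and their matched concatenation) and at finite
    acid-diffusion scale separation by solving the traveling-wave
    boundary-value problem with unknown wave speed.  Classifies benign,
    malignant no-gap, and malignant (acellular) gap regimes, computes the
    longitudinal spectrum of the front linearization, the transverse
    long-wavelength stability coefficient via the adjoint solvability
    condition together with its singular-limit asymptotics, and verifies the
    predicted interfacial instabilities in two-dimensional comoving-frame
    simulations.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    igraph,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
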