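Package: odorscape
Title: Odor Landscape Modeling, Gas-Sensor Calibration, and Chemotaxis
    Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for flow-chamber odor-landscape experiments with small
    animals. Calibrates metal-oxide gas-sensor arrays against a reference
    photo-ionization detector, models stationary odor plumes by
    convection-diffusion, simulates odor-agar interaction with a
    reaction-convection-diffusion solver and a pre-equilibration protocol,
    reconstructs two-dimensional concentration and gradient fields from
    sparse sensor arrays, and quantifies chemotaxis strategies (biased
    random walk, weathervaning, drift velocity) from animal trajectories.
    Includes an agent-based generator of worm- and larva-like navigators
    and synthetic sensor recordings for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
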