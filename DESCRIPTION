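Package: haircycle
Title: Multi-Scale Simulation of Hair Follicle Cycling and Skin-Wide Growth Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the mouse hair growth cycle as an excitable
    activator-inhibitor system. A single follicle is modeled as a moving
    one-dimensional domain carrying reaction-diffusion dynamics of two
    ligand-receptor signaling pathways (an activator such as WNT and an
    inhibitor such as BMP); the spatial mean of bound-receptor differences in
    the bulge drives growth and two phase checkpoints, producing autonomous
    cycling between anagen-like and telogen-like phases. Follicles are
    coupled on 1D arrays and 2D grids through inter-follicular ligand
    exchange, supporting heterogeneous skin domains (fast-cycling ventral
    stripes, hyper-refractory ear-like regions) and wave-breaking geometry
    (barriers and apertures). Includes pattern metrics (anagen onset maps,
    asynchrony persistence, bilateral symmetry, wavefront distortion),
    JSON scenario configuration with named presets, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
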