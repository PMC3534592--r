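Package: eitdbar
Title: D-Bar Reconstruction for Two-Dimensional Electrical Impedance
    Tomography via Sinc-Convolution
Version: 0.1.0
Authors@R:
    person("EIT", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete two-dimensional D-bar reconstruction chain for
    electrical impedance tomography (EIT) on disk domains: a complete
    electrode model (CEM) finite element forward solver with trigonometric
    current patterns, discrete Neumann-to-Dirichlet / Dirichlet-to-Neumann
    map construction, the truncated Born-approximate scattering transform,
    a sinc-convolution solver for the weakly singular D-bar integral
    equation using real-linear GMRES, and GREIT-style figures of merit
    (amplitude response, position error, ringing, resolution, shape
    deformation) together with convergence-rate and degree-of-truth
    diagnostics.  Includes synthetic phantom generators (chest model,
    rotating circular target), delimited-text interchange formats, a
    minimal MATLAB v5 reader for experimental dumps, and a command-line
    pipeline (simulate / reconstruct / evaluate / sweep).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
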