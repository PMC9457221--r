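Package: cora
Title: Quantifying Biological Feedback Control by Mathematically Controlled Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the contribution of a feedback loop to adaptation in an
    ODE-defined biochemical system. For a designated feedback signal and
    controlled species, the package constructs the locally analogous system
    without feedback (the feedback signal frozen to its steady-state value),
    applies the same small parameter perturbation to both systems, and reports
    the control ratio: the steady-state log-change of the controlled species
    with feedback relative to without. Includes a stiff-integration plus
    Newton steady-state solver with stability diagnostics, parameter sweeps
    and two-parameter grids, a library of feedback motifs (antithetic
    integral feedback with an explicit annihilation complex, Hill-repression
    loops, an open-loop fixture), declarative JSON model documents, tidy and
    ggplot2 accessors, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
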