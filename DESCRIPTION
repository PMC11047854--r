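Package: flapwing
Title: Flapping-Wing Hovering Aerodynamics with a D3Q27 Lattice Boltzmann
    Solver and Virtual-Flux Immersed Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the hovering flight of a small insect (fruit-fly scale)
    with two rigid, zero-thickness rectangular wings driven by prescribed
    three-angle flapping kinematics, including the elevation oscillation at
    twice the wingbeat frequency that produces figure-eight wing-tip paths.
    The flow is solved with a normalized incompressible lattice Boltzmann
    method on the 27-velocity lattice; the moving wings are imposed with a
    virtual flux immersed-boundary reconstruction, and nested multiblock
    Cartesian grids with 2x refinement per tier keep the cost down.  Post
    processing covers lift, thrust and power coefficients, Q-criterion and
    helicity diagnostics, cycle averaging, the elevation-phase by Reynolds
    number efficiency sweep, its elliptical approximation, and the
    tangency-based estimate of the most efficient elevation phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
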