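Package: radars
Title: Radial Interaction-Space Model of Antibody Repertoire Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the humoral immune system as a radial
    interaction space in which antibody specificity is a direction in
    antigen shape space and binding free energy is the radial coordinate.
    Provides unit-safe thermodynamic conversions between binding free
    energy and equilibrium constants, the double-Pareto (log-Laplace)
    distribution of system equilibrium constants arising from
    exponentially sampled random-energy Gaussians, an agent-based
    simulation of B-cell development, germinal-centre affinity maturation
    and antigen regulation, and construction and measurement of the
    resulting scale-free antibody interaction network (degree-exponent
    estimation, greedy box-covering fractal dimension, and the
    golden-ratio fixed point linking the two).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
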