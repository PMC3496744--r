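Package: amykin
Title: Kinetic Modelling of Amyloid Fibril Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation tools for nucleated protein
    polymerization kinetics. Implements the truncated discrete
    nucleation/polymerization/fragmentation/coalescence ODE system
    (Becker-Doring type with binary breakage and Smoluchowski
    coagulation), its continuous size-structured PDE limit with a
    quasi-steady-state nucleation boundary condition solved by a
    conservative first-order upwind scheme, ready-made model
    configurations for polyglutamine (PolyQ) aggregation with a
    monomeric-conformer nucleus, Knowles-type breakable filaments with
    the two-moment reduction, and Xue-type step-rate growth with a
    hybrid discrete/continuum solver. Includes thioflavin-T and static
    light scattering observables, sigmoid curve descriptors (lag time,
    maximal slope), a multi-start CMA-ES least-squares fitting protocol
    on mass curves, nucleus-size model selection, and a synthetic-data
    generator for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
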