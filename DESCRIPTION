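Package: vofde
Title: Variable-Order Fractional Delay Differential Equations for Enzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates enzyme-substrate kinetics governed by a variable-order
    Caputo fractional derivative with constant time delays.  Provides a
    general product-integration predictor-corrector (Adams-Bashforth-Moulton)
    solver for vector systems D^{delta(t)} y(t) = f(t, y(t), y(t - tau)) with
    the order frozen at the current evaluation time, a classical fourth-order
    Runge-Kutta reference path for integer-order runs, the four-compartment
    enzyme model (substrate, free enzyme, enzyme-substrate complex, product)
    with positivity and conservation monitors, Lipschitz/uniqueness/
    Ulam-Hyers stability condition calculators with an empirical perturbation
    experiment, and reproduction utilities for the reference trajectory
    tables, including per-cell comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
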