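Package: cryoiif
Title: Cell Dehydration and Nucleation-Limited Intracellular Ice Formation
    during Freezing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled modelling of osmotic cell dehydration and intracellular
    ice formation (IIF) during linear cooling. Implements the Mazur-type
    membrane water-transport equation, heterogeneous ice nucleation rates for
    surface-catalyzed (SCN) and volume-catalyzed (VCN) mechanisms including a
    critical-volume gate that shuts nucleation off in strongly dehydrated
    cells, probability-of-ice-formation (PIF) curves, stochastic single-cell
    IIF event simulation, and two-stage pooled nonlinear least-squares
    estimation of membrane and nucleation parameters from multi-rate
    cryomicroscopy-style observation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
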