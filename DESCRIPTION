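Package: pklump
Title: Compatibility of Whole-Body PBPK, Lumped, and Compartmental
    Pharmacokinetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates whole-body perfusion-rate-limited physiologically
    based pharmacokinetic (PBPK) models, reduces them to lumped models by
    grouping kinetically similar tissues (lumped central compartment and
    non-eliminating tissues compartment), simulates classical one- and
    two-compartment models, and quantifies the compatibility of the three
    model families through non-compartmental AUC, clearance, central and
    peripheral distribution volumes, 2-fold acceptance criteria, an
    accuracy-of-AUC statistic, and the power-law relation between Vd/fu
    values of the lumped and compartment models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
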