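Package: popshift
Title: Cell-Cycle Population-Shift Analysis of Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and removing the recurrent slow-growth
    expression signature of gene-deletion compendia and for explaining
    stress-response expression profiles as cell-cycle population shifts.
    Provides first-singular-mode signature extraction and Gram-Schmidt
    removal, spline-governed deconvolution of bulk expression profiles
    into cell-cycle-phase mixtures with randomization and cross-validation
    controls, a discrete-time slot-model simulator of a cell population
    arrested at the START checkpoint, hypergeometric gene-set enrichment,
    doubling-time estimation from growth curves, and seeded synthetic-data
    generators with known ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
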