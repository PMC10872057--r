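Package: esdsim
Title: Individual-Based Simulation of Environmental Sex Determination Under Climate Warming
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Individual-based evolutionary simulation of species with
    temperature-dependent (environmental) sex determination facing abrupt
    climate warming. Sex is set by a switchlike logistic reaction norm with
    three evolving diploid loci: the pivotal temperature, the reaction-norm
    slope (nonlinear plasticity) and a linear shift of the pivotal
    temperature with annual climate. The package provides the genetic,
    climatic, sex-determination and demographic building blocks, an annual
    population cycle with frequency-dependent sex-ratio selection, scenario
    grids over warming and climate-variability treatments, replicate batch
    execution with reproducible seeding, outcome classification
    (extinction, loss of ESD, ESD maintained) and CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
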