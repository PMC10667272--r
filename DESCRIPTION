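Package: sensorkin
Title: Batch Fitting of Label-Free Biosensor Titration Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput analysis of label-free biosensor
    (SPR, SPRi, BLI) titration sensorgrams. Fits reference-subtracted
    titration series to the 1:1 Langmuir interaction model by global
    nonlinear least squares, with support for regenerative and
    non-regenerative (single-cycle) titrations, optional bulk-shift and
    dissociation-drift nuisance terms, local or global Rmax, automatic
    baseline alignment, blank-cycle subtraction, data thinning and
    automatic analyte concentration down-selection. Reports association
    and dissociation rate constants with standard errors, the derived
    equilibrium dissociation constant KD with propagated error, replicate
    summaries (%CV, fold range), CSV estimate tables and multi-page PDF
    reports. Includes a sensorgram simulator so the whole pipeline can be
    exercised without instrument data, plus readers for canonical long
    tables and wide exports in the style of Carterra LSA, Biacore T200
    and Octet instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
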