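Package: aobr
Title: Hydraulic and Community Analysis for Split-Feeding Baffled Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising compartmental anaerobic/oxic baffled
    reactors (A/OBR) operated with regular or split feeding. A tanks-in-series
    simulator with split feed streams generates tracer impulse responses and
    steady-state COD profiles; analysis functions compute residence time
    distribution (RTD) moments, hydraulic dead space, the axial dispersion
    number, the equivalent number of tanks in series, and a mixing-pattern
    classification. Companion modules compute Shannon-Wiener diversity from
    DGGE band-intensity tables and per-compartment COD-removal bookkeeping
    with stage summaries and one-way ANOVA comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    withr,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Matrix,
    optparse
Config/testthat/edition: 3
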