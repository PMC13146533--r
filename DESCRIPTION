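Package: phototherm
Title: Photothermal Agent Characterization from Temperature Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing photothermal agents from
    thermal-imager temperature logs. Implements the lumped-capacitance
    energy-balance model of a laser-irradiated cuvette with exact
    piecewise-exponential solutions, the cooling-curve linearization
    method that recovers the system time constant, the heat-transfer
    product hA and the photothermal conversion efficiency from
    heating/cooling traces, dye loading content and efficiency (DLC/DLE)
    from absorbance calibration curves, multi-cycle photostability
    metrics, and CCK-8 viability and relative tumor volume summaries.
    Includes seeded synthetic-data generators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
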