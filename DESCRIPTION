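Package: lyodry
Title: Simulation and Optimization of Pharmaceutical Freeze-Drying Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Heat- and mass-transfer modeling of vial lyophilization
    (freeze-drying) for pharmaceutical formulations. Provides a 0D
    lumped-capacitance freezing calculator, a 1D quasi-steady primary-drying
    simulator with time-stepping and product-length-division schemes,
    calibration of vial heat-transfer coefficients (Kv) from experimental
    drying times and of dried-cake resistance (Rp) from measured product
    temperature traces, a Quality-by-Design primary-drying design-space
    generator, and a constrained per-time-step optimizer that produces
    variable chamber-pressure and shelf-temperature profiles minimizing
    primary drying time.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
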