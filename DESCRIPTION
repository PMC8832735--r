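Package: sivent
Title: Model-Based Decision Support for Volume-Controlled Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies patient-specific respiratory mechanics (elastance,
    resistance) from ventilator pressure-flow data with integral-based
    nonnegative least squares, forecasts the next-interval elastance range
    with a conditional kernel-density transition model, forward-simulates
    every volume-controlled ventilation setting combination with a
    single-compartment lung model, and eliminates combinations that violate
    clinical pressure, tidal-volume and I:E safety thresholds (the VENT and
    SiVENT protocols). Includes a virtual-patient generator for end-to-end
    evaluation without patient data, CSV/JSON/YAML interfaces and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
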