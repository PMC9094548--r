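Package: pcvsim
Title: Closed-Loop Simulation of a Pressure-Controlled Mechanical Ventilator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pure-software testbench for pressure-controlled ventilation
    (PCV/SIMV). Couples a breath-cycle state machine with PID pressure
    control, spontaneous-breath triggering, a high-airway-pressure safety
    override and a clinical alarm manager to a single-compartment (R/C)
    test-lung and pneumatic-circuit model. Includes waveform analytics
    (PIP, PEEP, tidal volumes, rise time), an FDA-EUA/ISO-style condition
    grid and endurance harness, seeded event injection (patient efforts,
    pressure transients), CSV/YAML serialization and a command-line
    interface. The closed-loop stepper is implemented in C++ so multi-day
    endurance runs complete in seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
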