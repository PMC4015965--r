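Package: gtdesign
Title: Model-Based Design of Synthetic Genetic Transistors from
    Promoter-RBS Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-stage repressor-cascade gene circuit (a
    "genetic transistor") with fluorescent-reporter readouts, computes its
    steady-state input/output characteristic under stochastic parameter
    fluctuations, and selects promoter-RBS components and inducer
    concentrations by genetic-algorithm search so that the circuit matches a
    prescribed linear-amplifier or switch response.  Includes nonlinear
    least-squares identification of promoter-RBS kinetic strengths from
    fluorescence time courses, seeded synthetic-data generators for libraries
    and time courses, a design look-up-table builder, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
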