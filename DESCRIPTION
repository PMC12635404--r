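Package: hpkinetics
Title: Hyperpolarized NMR Kinetics and Exometabolome Profiling of CAR T Cell Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for real-time metabolic phenotyping of CAR T cell cultures by
    NMR. Implements the two-pool kinetic model of hyperpolarized substrate-to-
    product conversion under pulsed sampling (closed form, numerical ODE and a
    discrete-pulse simulator), least-squares estimation of the apparent rate
    constant and apparent T1s with flip-angle correction, Lorentzian spectrum
    synthesis with J-coupled doublets and window integration, summed-spectra
    quantification with an SNR detectability rule, DSS-referenced quantification
    of spent-versus-fresh culture medium over a 21-day feed schedule, and
    synthetic-data generators with embedded ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
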