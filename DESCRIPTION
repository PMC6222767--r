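Package: qmmbed
Title: Hybrid Short- and Long-Range Electrostatic Embedding for Non-Periodic QM/MM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking hybrid electrostatic-embedding schemes in
    non-periodic QM/MM calculations. Near-field molecular-mechanics point
    charges interact explicitly with the quantum-mechanical electron density,
    while far-field charges interact with a multipolar representation of the
    QM subsystem (Mulliken or ESP-fitted charges and dipoles), joined smoothly
    by switching functions (Step, Shift, Switch, LREC). Includes an SVD-based
    ESP charge/dipole fit on layered van der Waals surface grids, the
    projection of MM charges onto the ESP grid, a classical polarizable
    surrogate backend (charge equilibration plus induced atomic dipoles) that
    fulfils the SCF backend contract without a quantum-chemistry engine, a
    synthetic TIP3P-style water-box generator, and a convergence-scan suite
    reporting RMSDs of electrostatic and polarization energies, atomic
    charges, and vertical excitation energies against an all-charge reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
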