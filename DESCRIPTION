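Package: amorphstab
Title: Eutectic Phase Diagrams and Amorphous-Phase Stability Analysis for
    Multi-Drug Formulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for the physical-chemistry characterisation
    of binary and ternary drug eutectics and their amorphous counterparts:
    ideal-solution liquidus curves and eutectic points via the
    Schroeder-Van Laar equation, feature extraction from DSC thermograms
    (melting onset, solidus/liquidus, glass-transition midpoint, fusion
    enthalpy), Havriliak-Negami fitting of broadband dielectric spectra with
    a dc-conductivity term, Vogel-Fulcher-Tammann and Stickel-derivative
    analysis of structural relaxation maps (kinetic glass transition,
    fragility, isochronal temperatures, dynamic crossover), and
    normalized-permittivity isothermal crystallization kinetics. A
    deterministic synthetic-data module generates every input with known
    ground truth so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
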