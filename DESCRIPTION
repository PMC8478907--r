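Package: minicircletools
Title: Topology Arithmetic, Helical-Repeat Calibration, Cleavage-Site
    Mapping and Nuclease Kinetics for Supercoiled DNA Minicircles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of small covalently closed circular
    DNA (minicircles) probed with structure-specific nucleases.
    Implements exact linking-number arithmetic (Lk0, delta-Lk,
    superhelical density, nick phasing, and base-pair equivalents of
    torsional strain absorbed by melting or B-to-P-DNA conversion),
    estimation of the relaxed linking number Lk0 from topoisomer gel
    mobilities via a V-shaped mobility model and pooling of constructs
    into a helical-repeat estimate, triangulation of nuclease cleavage
    sites on circular sequences from restriction-fragment lengths with
    circular statistics, fitting of steady-state and biphasic cleavage
    kinetics with detection of supercoiling thresholds in rate
    profiles, and seeded forward generators that emulate the three gel
    measurement types so that every analysis stage has
    parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
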