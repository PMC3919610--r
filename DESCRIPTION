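Package: okacycle
Title: Stochastic Simulation and Quantification of Lagging-Strand Polymerase Cycling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discrete-event stochastic simulation of a coupled rolling-circle
    replication fork on an asymmetric-composition minicircle template, used to
    discriminate the collision and signaling models of lagging-strand
    polymerase cycling during Okazaki fragment synthesis. Includes
    Michaelis-Menten nucleotide-analog kinetics (dGTP, dGDPNP), chain-terminator
    (ddGTP) run-length statistics, an in-silico gap-fill assay, a synthetic
    alkaline-agarose densitometry lane generator, and the quantification
    statistics used on such gels: molar (number-weighted) mean Okazaki fragment
    length, primer utilization efficiency, and priming-frequency ratios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
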