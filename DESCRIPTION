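Package: dcjtrans
Title: DCJ Scenarios, Dependency Graphs and Implicit Transposition Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for double-cut-and-join (DCJ) analysis of gene orders:
    GRIMM-style genome input/output, breakpoint graph construction and
    component classification, the closed-form DCJ distance, construction and
    validation of shortest and proper DCJ scenarios, dependency graphs of
    scenarios with shortcut detection and independence (T1) reordering, and
    constructive recovery of implicit transpositions (weakly dependent DCJ
    pairs merged into 3-breaks) together with genome-only lower bounds on
    their rate in proper and shortest scenarios. Includes a seeded synthetic
    generator of genomes, scramble histories with planted transpositions and
    proper non-shortest detour scenarios, plus a pairwise report driver and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
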