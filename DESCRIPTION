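Package: starchfba
Title: Expression-Constrained Flux Balance Analysis of Diurnal Starch
    Metabolism in Ostreococcus tauri
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A quasi-steady-state, constraint-based model of chloroplast
    starch metabolism in the picoalga Ostreococcus tauri. Provides a
    mass-balanced reconstruction of starch polymerization and degradation
    (37 metabolites, 69 reactions, 43 genes), a deterministic linear
    programming core with the diel objective function, dynamic rescaling of
    reaction bounds from gene-expression time series (a time-resolved
    E-flux scheme), quasi-steady-state simulation of the 12h:12h light-dark
    cycle, cumulated starch-content trajectories, in-silico single-gene
    impact and deletion scans, flux-variability and robustness analyses,
    JSON/SBML serialization, and a synthetic diurnal expression generator
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
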