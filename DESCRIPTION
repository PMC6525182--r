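Package: rootAllometry
Title: Allometry-Based Nonlinear Analysis of Absorptive-Root Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a geometric stele/cortex model of absorptive roots and
    the analysis pipeline built on it: the proportion of root cross-sectional
    area occupied by the stele (PRS) derived from the tToS-diameter allometry,
    allometry-form nonlinear least-squares regressions of root tissue density
    and nitrogen on diameter, standardized major axis slope comparisons,
    phylogenetic comparative statistics (independent contrasts, Blomberg's K,
    Pagel's lambda, PGLS), a sampling-bias reconciliation analysis, and a
    synthetic trait-and-tree generator that emulates a global absorptive-root
    trait dataset so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    minpack.lm,
    nlme,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
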