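Package: osvzlineage
Title: Lineage Simulation and Division-Mode Inference for Outer
    Subventricular Zone Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic branching-process simulation of cortical progenitor
    lineages with a gene-gated critical window for seeding of the outer
    subventricular zone (OSVZ), retroviral single-daughter reporter
    segregation, BrdU pulse labeling and inter-layer migration delays;
    inference of symmetric/asymmetric division-mode mixtures from labeled-cell
    censuses, mitotic cleavage-plane angle classification and delamination
    arithmetic; and three-stage differential-expression screening by
    permutation ANOVA with temporal-profile classification and comparative-Ct
    qPCR fold changes. Synthetic-data generators emulate the clonal labeling
    designs, angle samples, expression matrices and Ct tables the pipeline
    consumes, so every stage is testable in closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
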