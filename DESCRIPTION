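Package: ctxcut
Title: Context-Specific Metabolic Model Extraction from Genome-Scale Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of context-specific metabolic models from genome-scale
    constraint-based models (GEMs) under one shared abstraction. Implements the
    three established method families: GIMME-like (GIMME, GIM3E) which maximise
    agreement with expression data while guaranteeing a required metabolic
    functionality; iMAT-like (iMAT, INIT, tINIT) which maximise the number of
    matches between reaction activity and data states; and MBA-like (MBA,
    mCADRE, FastCORE) which prune the network down to a flux-consistent model
    containing a core reaction set. Ships the shared flux-analysis substrate
    (FBA, FVA, blocked-reaction detection, reversible splitting, GPR mapping),
    a built-in dense simplex LP and branch-and-bound MILP solver, SBML/JSON
    model input-output, synthetic toy-model and evidence generators with known
    ground truth, brute-force oracles for testing, and a method-selection
    advisor. Results are tibbles with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
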