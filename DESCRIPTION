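Package: domainsim
Title: Executable Domain Models of Cellular Immune Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and executes three-level domain models of cellular
    immune systems: a system-level research context linking observed
    phenomena to expected emergent behaviours, mid-level activity networks
    ("perspectives") with propagating, interrupting and contributory
    relationships executed under stochastic token-flow semantics, and
    single-entity state machines with probabilistic (delta), timed (lambda)
    and logical transition guards over orthogonal regions and composite
    states. A cross-diagram consistency checker validates state machines
    against the compartment graph and the research context. A multi-agent
    stochastic engine binds the statecharts, compartmental migration rules,
    interaction rules and cytokine fields into population-level runs, and
    ships a complete model of murine experimental autoimmune
    encephalomyelitis (EAE) exhibiting autoimmune onset followed by
    regulatory-T-cell-mediated recovery. Models round-trip through a JSON
    document format and render to Graphviz DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
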