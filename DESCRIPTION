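Package: adoptnet
Title: Threshold-Driven Adoption Cascades on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analytical machinery for heterogeneous-threshold
    social contagion with spontaneous adopters and immune (unconcerned) nodes.
    Provides lognormal degree and threshold laws with moment-matching fits,
    configuration-model populations, a discrete-time Monte Carlo engine that
    emits adoption event logs, approximate master equations (AME) reduced to a
    pair of ordinary differential equations for the adopter density, cascade
    structure analytics (adoption networks, stable subgraphs, innovator-induced
    vulnerable trees), and estimators that recover the spontaneous adoption
    rate and the immune fraction from event logs by largest-component matching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
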