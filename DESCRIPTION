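Package: fashiongame
Title: Conformists and Rebels Playing the Fashion Game on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the fashion game, a binary-action
    network game mixing coordination (conformists), anti-coordination
    (rebels) and matching pennies (mixed pairs). Provides generators for
    Moore-neighbourhood torus lattices and Watts-Strogatz style small-world
    networks, the stochastic best-response dynamic with tunable updating
    probability, four cooperation indices (cooperation degree, average
    satisfaction degree, equilibrium ratio, complete ratio), exact
    equilibrium enumeration for small instances, lattice pattern statistics
    (continents, interior agents, maze streets), and tidy parameter-sweep
    and phase-transition experiment drivers with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
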