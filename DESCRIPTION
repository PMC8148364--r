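Package: bondnet
Title: Energy-Conserving Bond-Graph Modules for Lumped Vascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds lumped-parameter physiological models as energy-conserving
    bond-graph modules, composes them automatically through semantic annotations
    and auxiliary port variables, and simulates the resulting linear ODE systems.
    Vessel segments are generated from three reusable templates (initial,
    intermediate, terminal) with resistance, inertance and compliance computed
    from segment geometry; modules are merged pairwise by binding zero-defaulted
    auxiliary port variables, hierarchically lumped, and cloned for symmetric
    subtrees. Includes a two-term Gaussian cardiac inflow generator, per-junction
    power-balance auditing, and normalised root-mean-square-error trace
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    deSolve,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
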