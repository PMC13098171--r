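Package: driftsim
Title: Serial Dilution-Growth Simulation of Ecological Drift in Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates serial-passage dilution-growth experiments on synthetic
    microbial communities to study whether neutral ecological drift alone can
    drive a complex community down to a minimal, functionally complete
    consortium. Communities are integer abundance vectors over populations,
    optionally organised into functional groups with fixed carrying capacities
    (niche sizes) and sparse unidirectional inter-group interactions that
    modify growth probabilities. Each cycle dilutes the community by
    multinomial sampling with replacement and regrows it stochastically to its
    carrying capacity. Includes fixation/extinction/success-rate analysis
    across replicate trajectories, diversity metrics, scenario grid expansion
    with reproducible seed splitting, a scenario runner with resumable
    output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
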