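Package: ldflex
Title: Coarse-Grained Simulation and Morphometry of Lipid Partitioning
    into Lipid Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computational toolkit for studying how chain
    flexibility controls the partitioning of lipophilic solutes into
    lipid droplets. Provides a coarse-grained bead-spring model of a
    phospholipid monolayer over a triacylglycerol core, a Langevin
    (BAOAB) dynamics engine with cell-list nonbonded evaluation,
    collective variables for solute migration (migration depth,
    end-to-end distance, conformation order, orientation angle),
    well-tempered multiwalker metadynamics with free-energy-surface
    reconstruction and barrier extraction, steered constant-force
    pulling with Langevin friction-coefficient estimation, lipid-droplet
    morphometry (per-cell volume and surface-area scaling of terpene
    storage), and seed-deterministic synthetic-data generators for all
    pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
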