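Package: hydralk
Title: Hydration Free Energies of Linear Alkanes by Free Energy
    Perturbation, with Cavity-Based Well-Depth Reparameterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the hydration thermodynamics of linear
    alkanes in water at the united-atom level. Implements the volume-weighted
    free-energy-perturbation estimator over soft-core Lennard-Jones coupling
    windows, a cavity-decomposition procedure that reparameterizes the
    alkane-water Lennard-Jones well depth against experimental hydration
    free energies, analytic corrections for shifted and truncated pair
    potentials (mean energy from radial distribution functions, cutoff-shift
    terms, and long-range tails), temperature-dependence utilities, and a
    seeded Metropolis Monte Carlo simulator of a rigid united-atom alkane in
    a neutral Lennard-Jones solvent that generates per-window samples,
    trajectories and radial distribution functions for validating the
    estimators end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
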