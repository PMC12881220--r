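Package: allomcoef
Title: Allometric Normalisation Constants for Bioenergetic Food Web Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates allometric intercepts of metabolism and biomass
    production under Bayesian phylogenetic hierarchical models (PGLS with
    Pagel's lambda on Grafen-scaled trees), converts the intercepts into the
    allometric normalisation constants (coefficients) used by bioenergetic
    food web (BEFW) models, and quantifies the effect of alternative
    coefficient sets on simulated food-web persistence, biomass and
    stability via niche-model communities, ODE biomass dynamics and Type II
    ANOVA effect sizes. Includes a synthetic-data generator emulating
    genus-level rate compilations with Boltzmann temperature dependence and
    phylogenetically correlated intercept deviations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    car,
    MASS,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
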