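Package: hexpop
Title: Individual-Based Demo-Genetic Simulation on Hexagonal Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A forward-time, spatially explicit, individual-based simulator of
    eco-evolutionary dynamics on dynamic hexagonal-cell landscapes. Diploid
    individuals with ten unlinked five-allele loci live on a six-patch habitat
    mosaic whose movement barriers, barrier gaps, and habitat types change
    across scheduled epochs. The annual life cycle couples scramble competition
    for resources, monogamous pair formation, density-dependent reproduction,
    correlated random-walk natal dispersal with per-encounter barrier-gap
    permeability, and stage-, resource-, and genotype-dependent survival.
    Emergent observables include generation time, migrants per generation,
    per-capita homozygosity, allelic richness and evenness, heterozygosity
    deficit, isolation-by-distance correlograms, and per-patch demographic and
    adaptive-allele trajectories; genotype snapshots can be exported in
    STRUCTURE format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
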