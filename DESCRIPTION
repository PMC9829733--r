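Package: vgm
Title: Vagrancy of Migratory Birds Under Geomagnetic Disturbance and Solar Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies avian vagrancy as a continuous spatiotemporal rarity
    index (mean great-circle distance from a banding record to the nearest of
    many points simulated proportional to weekly species-specific relative
    abundance) and relates it to 21-day rolling geomagnetic and solar activity
    indices with hierarchical Bayesian gamma regression: species- and
    year-level random intercepts and slopes, trait-level regressions of
    species sensitivity on migration length and breeding latitude, Bayesian
    imputation of unknown age, a geomagnetic-by-solar interaction model,
    Bayesian R-squared, posterior predictive checks, and post-hoc tests of
    phylogenetic signal (Blomberg's K) and diel migration strategy. Includes
    a synthetic-world generator (abundance surfaces, autocorrelated index
    series, banding records, traits, phylogenies) with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    jsonlite,
    picante,
    rjags,
    stats,
    utils,
    zoo
Suggests:
    withr,
    geosphere,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
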