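Package: peatbudget
Title: Greenhouse-Gas and Nitrogen Accounting for Degrading Peatlands
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for global peatland greenhouse-gas accounting on
    equal-area cell tables: land-cover and climate reclassification into
    land-use x climate emission classes, country-level allocation of
    degraded-peatland statistics to per-cell degradation fractions,
    potential and actual emission mapping with explicit min/mean/max
    uncertainty ranges, carbon and nitrogen stock budgets from C/N
    stoichiometry, cumulative emission trajectories with pool exhaustion,
    a saturating mineral-soil sequestration curve with equivalence-point
    analysis, and a Michaelis-Menten land-degradation expansion scenario.
    Includes a seed-deterministic synthetic-world generator so every stage
    runs without external GIS sources.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
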