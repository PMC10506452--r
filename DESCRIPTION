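Package: killrate
Title: Pest Kill Rate and Life-Table Demography of Predator Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort life-table analysis of predator efficiency against a
    target pest. From per-individual daily records (survival, stage,
    fecundity, stage-resolved prey kills) it builds age-specific schedules
    (lx, mx, kx), computes the net consumption rate K0, mean predation time
    Tk and the pest kill rate km as the root of the Euler-Lotka equation
    with predation substituted for fertility, alongside the classical
    intrinsic rate of increase rm. Uncertainty is quantified by leave-one-out
    jackknife pseudovalues with t-based intervals, and rearing origins are
    compared by the Newman-Keuls sequential studentized-range test with a
    compact letter display. A seeded individual-based simulator generates
    cohorts with the statistical structure of a phytoseiid predation
    experiment so every stage of the pipeline is testable at desk scale.
License: MIT + file LICENSE
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
    jsonlite
Config/testthat/edition: 3
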