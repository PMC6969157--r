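Package: fisheryP
Title: Global Fishery and Aquaculture Phosphorus Budget Accounting
Version: 0.1.0
Authors@R:
    person("P2R", "Builder", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mass-balance accounting of phosphorus (P) transfers between
    aquatic systems and land driven by fisheries and aquaculture. Computes
    the P removed from aquatic systems by fish harvest (production times
    whole-body P concentration, with hierarchical taxonomic imputation of
    missing species concentrations), the P injected into aquatic systems by
    aquaculture feed and fertilizer (harvested P divided by culture-system
    phosphorus-use efficiency in six environment-by-taxon groups), and their
    net balance through time with Monte Carlo uncertainty summarised as
    interquartile ranges. Includes trend statistics (peak landward flux,
    zero-crossing year), continental aggregation, forward scenario
    projection with a P-neutrality solver, and a fully seeded synthetic-data
    generator for all five input tables so the whole pipeline is testable
    offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
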