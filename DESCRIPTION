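Package: acidonet
Title: Co-Occurrence Network Ecology of Acid-Adapted Nitrifier Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying slow-growing keystone taxa in soil
    microbial communities along pH gradients. Builds signed co-occurrence
    networks from amplicon or genome abundance tables (prevalence filter,
    log-transformed Pearson correlation, random-matrix-theory threshold
    selection), classifies node roles by within-module degree (Zi) and
    among-module connectivity (Pi), computes null-model-corrected cohesion,
    and simulates extinction cascades driven by abundance-weighted mean
    interaction strength (wMIS). Companion modules cover community screening
    (rarefaction, core-genus criteria, marker-correlated taxon screens,
    mean rrn copy number), cobalamin supply/demand genome classification,
    cross-cutting statistics (variance partitioning, free-ammonia
    equilibrium, nitrification rates), and DNA stable-isotope-probing
    density-fraction analysis. A synthetic-community generator with planted
    keystone structure makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
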