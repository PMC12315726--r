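Package: agenet
Title: Data-Driven Dense Subnetwork Analysis of Aging Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-wise regression of resting-state functional connectivity on
    age with covariate adjustment, adaptive extraction of dense age-related
    subnetworks from the resulting -log10(p) inference matrix, family-wise
    max-statistic permutation inference, mapping of extracted subnetworks onto
    predefined functional networks with cross-cohort replication summaries, and
    linear path (mediation) analysis linking age, white-matter measures,
    subnetwork connectivity, and a general cognitive score. Includes a
    synthetic-cohort generator with planted subnetworks so the full pipeline is
    testable without access to population imaging cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
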