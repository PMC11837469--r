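Package: irmsim
Title: Polygenic Truncation-Selection Modelling of Insecticide Resistance Under Insecticide Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics simulation of insecticide resistance
    evolution in mosquito vectors, treating resistance as a polygenic trait
    ("polygenic resistance score") under truncation selection. Implements the
    sex-specific Breeder's equation response with cross-resistance as a
    correlated response, conversion between resistance score, bioassay
    survival and field survival, two-stage linear insecticide-efficacy decay,
    exhaustive single-generation selection grids for monotherapy and mixture
    deployments, a two-deme (treated site plus untreated refugia)
    multi-generation simulator comparing sequential-monotherapy and mixture
    resistance-management strategies, and an individual-based Monte-Carlo
    cohort simulator used as a brute-force cross-check of the analytic
    selection differentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    tidyr,
    dplyr,
    readr,
    yaml,
    jsonlite,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
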