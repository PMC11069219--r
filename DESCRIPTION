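Package: sirhist
Title: Histology-Specific Standardized Incidence Ratios for Second Primary Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates second-primary-cancer risk from person-level
    cancer-registry records. Implements the conventional standardized
    incidence ratio (SIR) and a histology-specific SIR that stratifies by
    the histology group of the index tumor and uses reference rates
    excluding the same histology group, which removes the downward bias
    introduced by IARC/IACR multiple-primary registration rules. Includes
    rule engines for the IARC/IACR and SEER multiple-primary dialects,
    person-time tabulation across age/period/region strata, exact Poisson
    confidence intervals, a closed-form bias simulation with correction
    factors x = 1 - p, and a synthetic registry generator with known
    ground truth so the whole pipeline can be validated without
    access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
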