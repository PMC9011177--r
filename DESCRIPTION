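Package: pvburden
Title: Carrier Burden, Heterogeneity and Cumulative Risk for Rare
    Pathogenic Variants Across Cancer Types
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Case-control analysis of rare pathogenic-variant carrier
    status across multiple cancer types in biobank-style cohorts:
    dominant-model carrier collapsing from classified variant calls,
    age-adjusted logistic burden tests with carrier-count gating,
    between-gene heterogeneity of odds ratios (Cochran Q, I-squared,
    DerSimonian-Laird random effects), lifetime cumulative-risk
    (penetrance) estimation from odds ratios and age-band population
    incidence, regional founder-variant enrichment and family-history
    trend analyses, and a synthetic cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
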