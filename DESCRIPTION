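Package: cortexmr
Title: Two-Sample Mendelian Randomization for Gut Inflammation and
    Cortical Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) from GWAS summary
    statistics, built around the design linking gut-inflammation exposures
    (inflammatory bowel disease, Crohn's disease, ulcerative colitis, IL-6,
    IL-6 receptor subunit alpha) to cerebral-cortex surface area and
    thickness phenotypes. Provides summary-statistic ingestion and allele
    harmonization, instrument selection with F-statistic strength screening
    and greedy LD clumping, the inverse-variance-weighted (fixed and
    multiplicative random-effects), weighted-median and MR-Egger estimators
    behind a single mr_fit() interface, a sensitivity battery (Cochran's Q,
    Egger intercept, MR-PRESSO, leave-one-out, funnel data), a study
    orchestrator with Bonferroni correction and a three-tier significance
    classification, and a seeded synthetic two-sample GWAS generator with
    known causal truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
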