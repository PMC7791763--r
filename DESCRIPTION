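Package: fhconcord
Title: Concordance of Family History Risk and Actionable Germline Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of comprehensive family health histories and
    germline variants in a cancer gene panel, for population genomic
    screening cohorts. Provides triage of rare panel variants into
    clinically actionable and uncertain classes (frequency filtering,
    candidate selection routes, ACMG-AMP evidence combination), a
    configurable rules engine that stratifies four-generation pedigrees
    into increased versus average familial cancer risk, cohort-level
    concordance statistics with Altman relative risk and log-normal
    confidence intervals plus Fisher exact tests, and a synthetic cohort
    generator with Mendelian segregation and a penetrance model so that
    every pipeline stage runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
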