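Package: promiscuitrack
Title: Monitoring Drug Promiscuity Over Time from Dated Bioactivity Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for estimating how the apparent promiscuity of
    approved drugs (the number of distinct protein targets with reported
    activity) develops over time as bioactivity databases grow. Provides
    tiered confidence curation of compound activity records (assay
    relationship type, confidence score, measurement type and relation
    filters, with an order-of-magnitude consistency rule for repeated Ki/IC50
    measurements), structure-based drug-to-compound mapping by canonical
    SMILES identity, cumulative time-interval promiscuity profiling over 14
    release-year intervals, cross-database annotation comparison, target
    family analysis, PAINS substructure screening, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    ChemmineR,
    ChemmineOB,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
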