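Package: dipesignal
Title: Pharmacovigilance Signal Detection for Drug-Induced Pulmonary Edema
    from FAERS-Schema Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for spontaneous-report signal detection of
    drug-induced pulmonary edema (DIPE) on FAERS-schema quarterly ASCII
    data: cohort construction (case deduplication, healthcare-professional
    reporter filter, pre-existing-diagnosis exclusion), four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio, BCPNN information component, and the empirical-Bayes
    gamma-Poisson shrinker EBGM/EB05) with four-method consensus calling,
    confounder-adjusted logistic regression fitted by iteratively
    reweighted least squares, and stratified time-to-onset comparison by
    rank-sum tests.  A synthetic-FAERS generator with a known ground-truth
    manifest (injected drug-event effects, demographic confounding,
    stratum-shifted onset distributions, duplicate case versions, partial
    dates) makes every stage testable without the multi-gigabyte public
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
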