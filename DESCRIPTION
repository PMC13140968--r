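Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Adverse Event Reports
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII releases: ingestion and validation of the
    "$"-delimited DEMO/DRUG/REAC/THER/OUTC tables, FDA-recommended case
    deduplication, drug-name normalisation and exposure-cohort construction
    (immune checkpoint inhibitor plus platinum combination therapy versus
    monotherapies), four-algorithm disproportionality analysis (reporting odds
    ratio, proportional reporting ratio with Pearson chi-square, BCPNN
    information component, and the Multi-item Gamma Poisson Shrinker empirical
    Bayes geometric mean) with a joint signal gate, time-to-onset and
    demographic subgroup summaries, and a synthetic FAERS-format report
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
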