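Package: faersignal
Title: Disproportionality Signal Detection and Prioritization for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pharmacovigilance pipeline for FDA Adverse Event
    Reporting System (FAERS) quarterly ASCII extracts: report ingestion and
    case-version deduplication, four-algorithm disproportionality analysis
    (reporting odds ratio, proportional reporting ratio with chi-square,
    Bayesian confidence propagation neural network information component,
    and multi-item gamma Poisson shrinker), semiquantitative clinical
    priority scoring of detected signals, demographic stratification,
    serious versus non-serious report comparison, and Weibull time-to-onset
    failure profiling. Includes a synthetic FAERS-format report generator
    with planted drug-event associations so every pipeline stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
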