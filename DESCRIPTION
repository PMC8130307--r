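Package: adrsignal
Title: Pharmacovigilance Signal Detection from Electronic Health Records and
    Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-processing pipeline for active surveillance of adverse
    drug reactions (ADRs) across two kinds of real-world data. From an
    OMOP-CDM-style electronic health record (EHR) extract it builds
    new-user drug cohorts, applies a case definition, performs 1:1
    propensity-score matching on demographic and utilisation covariates,
    and estimates drug-outcome hazard ratios by Cox regression. From a
    spontaneous reporting system (SRS) corpus it builds drug-reaction 2x2
    contingency tables and computes reporting odds ratios. Per-source
    signals are pooled by Mantel-Haenszel fixed-effect and
    DerSimonian-Laird random-effects meta-analysis of risk ratios.
    Includes converters for pure-tone audiometry thresholds into
    normal/abnormal hearing outcomes, and synthetic EHR and SRS
    generators with planted effect sizes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
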