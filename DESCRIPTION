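Package: matgrade
Title: Degrees of Maternal Morbidity Surveillance for Perinatal Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies perinatal registry records into a maternal-morbidity
    severity gradient (maternal death, near miss, potentially life-threatening
    condition, less severe morbidity, none) using configurable rule-based
    criteria, computes the WHO-style surveillance indicator panel (maternal
    mortality ratio, near-miss ratio, severe-maternal-outcome ratio and
    related rates per live births), builds severity-stratified contingency
    tables with chi-square tests corrected for the cluster (primary sampling
    unit) design effect, and estimates crude and adjusted prevalence ratios
    with cluster-robust confidence intervals. Ships a synthetic registry
    generator with known severity mixture, covariate effects, cluster
    structure and missingness so every stage is testable without access to
    confidential registry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
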