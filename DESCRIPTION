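Package: abdoscreen
Title: Multi-Disease Cost-Effectiveness Model of One-Off Upper Abdominal CT Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A health-economic decision model evaluating the addition of a
    one-off upper abdominal CT screen to thoracic CT lung cancer screening.
    A short-term screening and diagnosis decision tree feeds lifetime
    annual-cycle cohort Markov models for ten cancers, abdominal aortic
    aneurysm and a no-disease population. Includes screen-detectable
    prevalence derivation from incidence, dwell times and scan
    sensitivity/coverage; calibration of symptomatic diagnosis rates to
    stage-at-diagnosis distributions; discounted cost, life-year and QALY
    aggregation with half-cycle correction; incremental cost-effectiveness,
    net-monetary-benefit decomposition by disease, probabilistic sensitivity
    analysis, scenario analysis, and expected value of (partial) perfect
    information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
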