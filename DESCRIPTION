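Package: herdmis
Title: Herd-Level Impact Analysis of Management Information System Adoption
    in Dairy Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the productive, reproductive, health and
    economic impact of adopting a herd management information system (MIS)
    in dairy herds. Derives herd-year performance traits (age at first
    calving, days open, daily milk yield, productive life, mastitis and
    lameness incidence) from animal event records, classifies herds by
    adoption level from record availability, fits linear mixed models with
    a between-herd random intercept and first-order autoregressive
    within-herd serial correlation, computes marginal (least-squares)
    means by adoption level and follow-up year, and evaluates the
    intervention economically through partial budgeting with deterministic
    scenario and Monte-Carlo sensitivity analysis. A synthetic herd-event
    generator reproduces the statistical structure of national dairy
    recording databases so the whole pipeline is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
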