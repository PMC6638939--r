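Package: akicourse
Title: Recurrent Acute Kidney Injury Episodes and Chronic Kidney Disease
    Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and stages acute kidney injury (AKI) episodes from
    longitudinal serum-creatinine series using relative-change and
    absolute-increase e-alert rules with a seven-day nadir-of-function
    merge, partitions each patient's follow-up into inter-episode periods,
    and analyses chronic kidney disease (CKD) progression with
    cause-specific Cox competing-risks models (stage 1 AKI, stage 2/3 AKI,
    renal replacement therapy, death), Aalen-Johansen cumulative incidence
    curves, and a linear mixed model for the MDRD eGFR trajectory with a
    random intercept and an exponentially correlated serial process fitted
    by maximum likelihood. A seeded synthetic-cohort generator emulates the
    data structure of an all-cause CKD cohort (irregular laboratory draws,
    injected creatinine excursions, competing event times) so that the full
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    cmprsk,
    withr
Config/testthat/edition: 3
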