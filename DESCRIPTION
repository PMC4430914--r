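Package: cvdscreen
Title: Chart-Based Cardiovascular Risk Screening, Decision Support and
    Field Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Point-of-care assessment of 10-year absolute cardiovascular
    disease (CVD) risk from colour-coded lookup charts (low- and
    high-information variants), rule-based detection of clinical
    sub-conditions (clinically high risk, impaired fasting glucose,
    overweight/obesity, hypertension), and a data-driven referral,
    medication and next-visit recommendation engine for community
    health-worker screening programmes. Includes counterfactual risk
    projection, an evaluation framework for click-stream logs (procedure
    and step timing, sequential bootstrap confidence intervals for mean
    procedure time, Bluetooth-adoption and recommendation-dissemination
    rates, glucose manual-entry error reconciliation against glucometer
    memory, Likert usability summaries), and seeded synthetic generators
    for screening cohorts, per-worker click-event streams and glucometer
    memories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
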