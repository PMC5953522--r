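Package: hewcost
Title: Time-Driven Activity-Based Costing for Community Health Worker Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A time-driven activity-based costing (TDABC) pipeline for
    community health worker programs, built around Ethiopia's Health
    Extension Program. Ingests time-motion observation logs and district
    (Woreda) salary surveys, summarizes per-activity encounter statistics
    with a three-standard-deviation outlier rule, derives salary cost per
    billable minute with a seasonal-campaign opportunity-cost uplift, applies
    non-salary cost-recovery multipliers, and assembles urban and rural
    full-cost-recovery fee schedules in birr and US dollars together with a
    printable encounter tally form. Includes a seeded synthetic-data
    generator that emulates the time-motion study structure so the whole
    pipeline is testable without field data, and a regression comparator
    against packaged reference fee tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
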