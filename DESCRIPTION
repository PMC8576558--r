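Package: opioidalerts
Title: Real-Time Duplicate-Indication Alerts for As-Needed Opioid Orders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rule-based detection of inpatient as-needed (PRN) opioid orders
    with duplicate pain-level indications, for opioid stewardship and
    medication safety surveillance. Implements a five-alert duplicate
    detection bundle over medication order streams (explicit mild, moderate
    and severe pain-level duplicates; unclear-indication duplicates; and
    patient-controlled analgesia alongside intravenous PRN opioids) with
    operating-room censoring and 24-hour throttling; a five-category
    appropriateness classifier mapping duplicate sets to pharmacist
    interventions; patient-level diagnostic validation with Clopper-Pearson
    exact binomial confidence intervals; a seeded synthetic order-stream
    generator with ground-truth labels; and readers and writers for CSV,
    JSON-lines and a minimal HL7-v2-like pharmacy order format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
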