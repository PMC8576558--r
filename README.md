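# opioidalerts

Rule-based clinical decision support for opioid stewardship: real-time
detection of inpatient **as-needed (PRN) opioid orders with duplicate pain
indications**, appropriateness classification with recommended pharmacist
interventions, and diagnostic validation of the alert bundle — plus a
labeled synthetic order-stream generator so the whole stack runs with no
protected health information.

It is written for pharmacists, medication-safety teams, and informaticists
who want to prototype, audit, or re-validate duplicate-therapy alerting
logic outside a live EHR.

## What it detects

A patient's PRN opioid orders should cover mutually exclusive pain levels on
the 1–10 numeric rating scale: mild (1–3), moderate (4–6), severe (7–10),
with combined ranges 1–6 and 4–10 also in use. Five alert rules are
evaluated over a patient's co-active, opioid, PRN/PCA orders (orders
verified in operating rooms or procedural areas are censored):

| Alert | Fires when |
|---|---|
| Opioids PRN for mild pain | ≥ 2 orders' score ranges overlap 1–3 |
| Opioids PRN for moderate pain | ≥ 2 orders' score ranges overlap 4–6 |
| Opioids PRN for severe pain | ≥ 2 orders' score ranges overlap 7–10 |
| Opioids PRN for pain | ≥ 1 order with an unclear indication, ≥ 2 orders total |
| Opioid PRN PCA | a PCA order alongside an intravenous non-PCA PRN opioid |

Overlap of score ranges — not equality of labels — defines "same pain
level", so a 4–10 order duplicates both a 4–6 and a 7–10 order. Alerts are
throttled to one activation per patient per rule per 24 hours. Detected
duplicate sets are classified by three attributes (same route+formulation,
clear administration instructions, linked order group) into five categories,
only the first of which is appropriate; category 5 (same route and
formulation) always recommends discontinuing all but one order.

Bundle validation is patient-level diagnostic testing: sensitivity,
specificity, PPV, NPV and accuracy against a chart-review reference
standard, each with a Clopper–Pearson exact 95% interval,
p̂ ∈ [qβ(α/2; x, n−x+1), qβ(1−α/2; x+1, n−x)].

## Worked example

```r
library(opioidalerts)

feed <- order_feed(data.frame(
  order_id    = c("A1", "A2", "A3"),
  patient_id  = "P17",
  drug_name   = c("oxycodone 5 mg", "hydromorphone 0.5 mg", "tramadol 50 mg"),
  route       = c("oral", "IV", "oral"),
  formulation = c("tablet", "injection", "tablet"),
  is_prn      = TRUE,
  prn_indication_text = c("PRN for severe pain (score 7-10)",
                          "PRN for severe pain (score 7-10)",
                          "PRN for pain"),
  start_time  = c("2024-03-04 09:00", "2024-03-04 09:00", "2024-03-05 14:00"),
  verify_location_class = "acute_care"))

stream_detect(feed)
#>                     rule_name patient_id            fired_at triggering_order_ids bundle_version
#> 1 Opioids PRN for severe pain        P17 2024-03-04 09:00:00                A1;A2              2
#> 2 Opioids PRN for severe pain        P17 2024-03-05 14:00:00                A1;A2              2
#> 3        Opioids PRN for pain        P17 2024-03-05 14:00:00             A1;A2;A3              2
```

The two severe orders duplicate each other at 09:00; the alert repeats the
next day (the duplication persisted past the 24-hour throttle window and a
new order event re-evaluated the patient), and the scale-free "PRN for pain"
order triggers the implicit unclear-indication alert. Classifying the severe
pair:

```r
assess_duplicates(feed[feed$order_id %in% c("A1", "A2"), ])
#> Duplicate assessment: category 4 (inappropriate)
#>   same route+formulation: FALSE | clear instructions: FALSE | linked: FALSE
#>   intervention: clarify_and_link

recommend_instruction(feed[1:2, ])
#> [1] "Give if patient can receive oral tablet medication."
#> [2] "Give if patient is not able to receive oral medication."
```

Different formulations without instructions or linking: the recommended fix
is to add the standard conditional instructions and link the orders, not to
discontinue.

Validating the bundle against the deterministic 201-patient cohort:

```r
fx <- make_step2_fixture()
log <- stream_detect(fx$orders, bundle_version = 1)
cm  <- confusion_matrix(alert_flags(log, fx$labels$patient_id, fx$window),
                        fx$labels$has_duplicate)
performance(cm)
#> Alert bundle performance (patient level)
#>   sensitivity  94%  (95% CI 80%-99%)  [32/34]
#>   specificity  96%  (95% CI 92%-98%)  [160/167]
#>   ppv          82%  (95% CI 66%-92%)  [32/39]
#>   npv          99%  (95% CI 96%-100%)  [160/162]
#>   accuracy     96%  (95% CI 92%-98%)  [192/201]
```

`generate_orders(generator_config(...))` produces seeded random cohorts with
per-patient ground-truth labels and tunable false-positive/false-negative
noise modes; see the methods vignette
(`vignettes/duplicate-opioid-alerts.Rmd`) for the generator's design and its
limits.

## Command line

A thin Rscript front end wraps the same functions:

```sh
Rscript inst/cli/opioidalerts.R simulate --seed 1 --n-patients 200 \
    --out-orders orders.csv --out-labels labels.csv
Rscript inst/cli/opioidalerts.R detect --input orders.csv --output alerts.csv \
    --bundle-version 2 --throttle-hours 24
Rscript inst/cli/opioidalerts.R validate --alerts alerts.csv --labels labels.csv
```

Feeds are read as CSV, JSON-lines, or a documented minimal HL7-v2-like
pipe-delimited format (`read_order_feed(..., format = "hl7lite")`).

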