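---
title: "Detecting and resolving duplicate PRN opioid orders: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and resolving duplicate PRN opioid orders: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidalerts)
```

## The problem

Hospitalized patients are commonly prescribed as-needed (PRN) opioids whose
indication is a pain-score range on the 1–10 numeric rating scale: mild
(1–3), moderate (4–6), severe (7–10), or the combined ranges 1–6 and 4–10.
When two co-active PRN opioid orders cover the same pain level, the bedside
nurse faces an ambiguous instruction; duplicate administration and
opioid-related adverse events become more likely. Accreditation standards
therefore ask for mutually exclusive pain levels across a patient's PRN
opioid orders.

`opioidalerts` implements a real-time surveillance bundle for this problem:
it watches an order stream, fires one of five named alerts when a patient's
co-active PRN/PCA opioid orders duplicate a pain level, classifies each
detected duplicate set into a five-category appropriateness schema with a
recommended pharmacist intervention, and scores the bundle against a
patient-level reference standard using exact binomial statistics.

## The alert bundle

Orders enter detection only when they are opioids and either PRN or
patient-controlled analgesia (PCA). Orders verified in an operating room or
procedural area are censored: those orders are transient, live in a
different record workflow, and would flood the bundle with noise.

The five rules, evaluated over the eligible orders of one patient at one
time point:

* **Opioids PRN for mild / moderate / severe pain** (explicit duplicates):
  fires when two or more orders' score ranges overlap that level's range.
  Overlap of ranges — not equality of labels — defines "same pain level", so
  a combined 4–10 order duplicates both a 4–6 and a 7–10 order.
* **Opioids PRN for pain** (implicit): fires when at least one order has an
  unclear indication (no recognizable pain scale) and at least two eligible
  orders exist at all.
* **Opioid PRN PCA** (implicit): fires when a PCA order co-exists with at
  least one intravenous non-PCA PRN opioid. Oral partners do not fire this
  rule; the risk addressed is a second intravenous opioid alongside the
  pump.

Evaluation is event-driven: `stream_detect()` evaluates the bundle at each
order-start event (the real-time proxy for order verification), not by
periodic polling, and does not re-evaluate at discontinuations. A throttle
then suppresses repeat activations: at most one alert per patient per rule
per 24 hours (the scope is configurable to one alert per patient of any
kind, the "patient-based" review mode). Both the window and the scope are
tunable; 24 hours per (patient, rule) is the default because the five rules
name distinct clinical situations a reviewer would want to see separately.

Two bundle versions exist. Version 1 recognizes empty indications and plain
scale-free pain text ("PRN for pain") as the unclear-indication trigger.
Version 2 — the default — additionally recognizes the forms "breakthrough
pain" and "any pain", which version 1 deliberately ignores. This mirrors how
such bundles evolve in practice: the unclear forms are discovered by
validation and added afterwards.

Detection never reads `linked_group_id`. Live order feeds typically do not
carry the EHR's order-linking information, so the detector must work without
it; linking is consulted only at the chart-review (classification) layer.
This asymmetry is deliberate and load-bearing: it is one documented source
of false-positive alerts.

## Parsing PRN indications

`parse_indication()` is total: every string maps to exactly one category.

1. A numeric score range ("(score 4-6)", "score 4 to 6") is extracted first
   and beats any surrounding words. A range equal to one of the five
   standard ranges maps to its category; a non-standard range maps to the
   *narrowest enclosing* standard category when that is unique (2–5 is
   inside 1–6 only; 4–5 is inside 4–6, 1–6 and 4–10, and 4–6 is narrowest),
   and to `unspecified` otherwise (nothing encloses 1–10).
2. Otherwise a prioritized, case-insensitive word-pattern table applies
   (first match wins); it ships as an editable CSV config
   (`read_parse_rules()`) because order-template vocabulary drifts between
   sites.
3. Anything else — including empty text — is `unspecified`.

PCA orders are categorized `pca` regardless of text.

## The appropriateness schema

Three attributes of a duplicate set drive the classification: whether any
pair shares both route and formulation; whether every order carries clear
administration instructions; and whether all orders sit in one linked order
group.

| Category | Same route+formulation | Clear instructions | Linked | Appropriate | Intervention |
|---|---|---|---|---|---|
| 1 | no | yes | yes | yes | none |
| 2 | no | no | yes | no | clarify instructions |
| 3 | no | yes | no | no | link orders |
| 4 | no | no | no | no | clarify and link |
| 5 | yes | any | any | no | discontinue all but one |

Design choices the schema leaves open, and how this package resolves them:

* *Clarity of instructions* has no operational definition in the source
  policy beyond its example templates, so "clear" is operationalized as a
  configurable pattern list seeded with the conditional "give if …" phrasing
  of the standard templates (`default_clear_patterns()`).
* *How many orders must be clear*: all of them. Requiring all-but-one would
  leave the nurse with one ambiguous order, which is the situation the
  schema exists to prevent.
* *Sets larger than two*: "same route and formulation" is evaluated
  pairwise, and any matching pair forces category 5 — that pair alone is
  already the hard duplicate.

For category-5 sets, `discontinuation_rationale()` ranks candidates:
older start date first, deterministic tie-break on order id, with optional
reason codes (no recent administration, documented adverse event, no
associated order set) emitted only when the corresponding chart columns are
supplied.

## Validation statistics

Validation is at the patient level — a patient is test-positive when at
least one alert fired in the observation interval and condition-positive
when chart review found at least one duplicate set — because medication
profile review happens per patient, not per alert.

All intervals on proportions are Clopper–Pearson exact intervals (beta
quantile form), two-sided by default, with a one-sided lower-bound variant
for small positive-only screening samples (for x = n successes the closed
form is `(1 - confidence)^(1/n)`; for 10/10 at 97.5% that is 69.15%, which
we report as computed rather than rounding up). Exact intervals are
conservative: empirical coverage is at least nominal, which the test suite
checks by simulation. Display rounding is half-up to integer percent
(`percent_round()`); raw proportions are always retained in machine output.
One consequence worth knowing: the exact interval for 32/39 is
66.47%–92.46%, i.e. 66–92 after rounding — summaries produced with other
software or transcription conventions sometimes differ by a point, and this
package always reports the computed value.

Pharmacist time effort is summarized by a saturated categorical regression:
ordinary least squares of minutes on the four mutually exclusive action
categories without intercept, so fitted values are exactly the per-category
sample means and confidence intervals use the pooled residual variance (not
per-group variances). With a single category the model degenerates to the
sample mean with its usual standard error.

## The synthetic generator

`generate_orders()` emulates a 5-day cross-sectional observation window on
acute-care/ICU wards. Its defaults are the study conditions: 201 patients,
1.2 background orders per patient (Poisson), the order-level category mix
(1% mild, 51% moderate, 39% severe, 1% mild-and-moderate, 2%
moderate-and-severe, 2% PCA, 4% unspecified), 17% of patients carrying a
planted duplicate set, and a duplicate-type split of 35% moderate / 26%
severe / 21% both levels / 18% unclear-indication.

Two design points matter for interpreting tests run on generated data:

* **Accidental duplicates are staggered, not resampled.** Background order
  categories are i.i.d. draws from the category mix. When a drawn order
  would conflict with a co-active order of the same patient, its start is
  deferred until the earlier order ends (sequential therapy) instead of
  redrawing its category. Category frequencies therefore match the
  configured mix exactly (the chi-square goodness-of-fit invariant is
  asserted at `duplicate_prevalence = 0`, since planted sets intentionally
  add moderate/severe mass on top of the background mix), and the
  per-patient duplicate labels are exactly Bernoulli(prevalence).
* **Errors are explicit noise modes**, because real false positives and
  false negatives have causes. `parser_evading` rewrites one planted
  indication to "breakthrough pain"/"any pain" (invisible to bundle
  version 1); `procedural_censor` verifies one planted order in a
  procedural area; `chart_only` keeps one planted order out of the feed
  entirely (visible only to the chart reviewer); `transient_fp` gives a
  non-duplicate patient a short-lived duplicate pair that alerts and is
  resolved before review. All default to 0: with no noise the detector and
  the labels agree perfectly, by construction. The three false-negative
  modes act on planted sets of exactly two orders; four-order
  both-level sets keep firing through the unaffected level, so they are
  left untouched.

What the generator does *not* model: medication administrations, pain-score
trajectories, dose equivalence, length-of-stay realism, or correlation
between a patient's order count and their duplicate status. Passing tests
on generated data therefore demonstrate the correctness of the rule logic
and the validation arithmetic under the stated conditions, not the bundle's
performance on any particular hospital's feed.

`make_step2_fixture()` is the deterministic companion: a fixed 201-patient
cohort whose 241 review-time orders match the reference category counts
exactly, with 34 truth-positive patients (12 moderate / 9 severe / 7 both /
6 unclear), one false negative engineered through a "breakthrough pain"
indication under bundle version 1, one through operating-room censoring, and
seven false positives through transient discontinued-order timing. Run
through `stream_detect(bundle_version = 1)` it yields the confusion matrix
(32, 7, 2, 160):

```{r fixture}
fx <- make_step2_fixture()
log <- stream_detect(fx$orders, bundle_version = 1)
flags <- alert_flags(log, fx$labels$patient_id, fx$window)
cm <- confusion_matrix(flags, fx$labels$has_duplicate)
cm
performance(cm)
```

Under bundle version 2 the breakthrough-pain miss is recovered (the false
negatives drop from 2 to 1) — the motivation for versioning the bundle.

## Numerical and interface conventions

* Timestamps are timezone-naive ISO 8601 at minute precision; one feed is
  one facility clock (held as UTC internally). Seconds are truncated.
* Activity windows are half-open `[start, end)`: a discontinued order stops
  alerting exactly at its end timestamp; an absent end means open-ended.
* Route, formulation and verification-location strings are normalized to
  closed token sets at ingest; unknown strings become `"other"` so rule
  matching is deterministic. Feeds need not be pre-sorted: `stream_detect()`
  derives and orders the event sequence itself.
* Alerts are emitted in the fixed rule order (mild, moderate, severe, pain,
  PCA) with sorted, semicolon-joined triggering order ids, so logs are
  byte-reproducible.
* The HL7-lite reader is a documented minimal pipe-delimited dialect — a
  stand-in for a site's real interface, not a certified HL7 v2
  implementation.

## Problem sizes used in the shipped checks

The test suite exercises the detector against a brute-force pairwise oracle
on 1,000 random order sets of up to 8 orders, throttling on randomized
multi-patient feeds, interval coverage by simulation (10,000 replicates at
n = 20), the category-mix invariant on a ~5,400-order cohort, and
prevalence calibration on 2,000 patients; synthetic validation cohorts of
300–800 patients are used for the noise-free/noisy accuracy contrasts.
These sizes give stable verdicts for the properties being checked while
keeping the default test run fast.

## Known limitations

* The parser is a rule table, not an NLP model; free-text indications
  outside the configured vocabulary fall to `unspecified`, which is safe for
  alerting (they trigger the implicit rule in company of another order) but
  coarse.
* Non-pain PRN indications (nausea, bowel regimen) are out of scope.
* Dose-equivalence reasoning (morphine milligram equivalents) and
  drug–drug interaction logic are out of scope.
* The detector evaluates only at order starts; a duplicate created by
  *shortening* another order's window is not re-announced.
* Reported pharmacist minute values from any particular deployment are not
  reproducible from this package; the time-effort model is validated
  structurally (saturated-model recovery of known means).
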