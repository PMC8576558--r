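# The alert bundle: five duplicate-indication rules over a patient's
# co-active PRN/PCA opioid orders, with operating-room/procedural censoring
# and per-(patient, rule) 24-hour throttling.

#' Alert rule names
#'
#' The five alert names of the bundle, in the fixed emission order used
#' throughout the package: the three explicit per-level rules, the
#' unclear-indication rule, and the PCA rule.
#'
#' @return Named character vector (names \code{mild}, \code{moderate},
#'   \code{severe}, \code{pain}, \code{pca}).
#' @export
alert_rule_names <- function() {
  c(mild = "Opioids PRN for mild pain",
    moderate = "Opioids PRN for moderate pain",
    severe = "Opioids PRN for severe pain",
    pain = "Opioids PRN for pain",
    pca = "Opioid PRN PCA")
}

empty_alert_log <- function() {
  data.frame(rule_name = character(), patient_id = character(),
             fired_at = as.POSIXct(character(), tz = "UTC"),
             triggering_order_ids = character(),
             bundle_version = integer(), stringsAsFactors = FALSE)
}

#' Orders eligible for duplicate evaluation at a time point
#'
#' Keeps opioid PRN/PCA orders active at \code{t}; censors orders verified in
#' an operating room or procedural area (their temporary perioperative nature
#' would otherwise flood the bundle with noise).
#'
#' @param orders An [order_feed()] data.frame.
#' @param t Evaluation timestamp.
#' @return The eligible subset of \code{orders}.
#' @export
eligible_orders <- function(orders, t) {
  keep <- orders$is_opioid & (orders$is_prn | orders$is_pca) &
    is_active(orders, t) &
    !orders$verify_location_class %in% censored_locations
  orders[keep, , drop = FALSE]
}

#' Evaluate the alert bundle for one patient at a time point
#'
#' Fires, over the eligible orders at \code{t}:
#' \itemize{
#'   \item \strong{mild / moderate / severe}: when two or more orders'
#'     score ranges overlap that level's range (so a combined 4-10 order
#'     duplicates both a 4-6 and a 7-10 order);
#'   \item \strong{Opioids PRN for pain}: when at least one order has an
#'     unclear indication (no recognizable pain scale) and at least two
#'     eligible orders exist in total; under \code{bundle_version = 1} the
#'     "breakthrough pain" / "any pain" forms do not count as the unclear
#'     trigger (they joined the bundle at version 2);
#'   \item \strong{Opioid PRN PCA}: when a PCA order co-exists with at least
#'     one intravenous non-PCA PRN opioid of any pain level.
#' }
#' Each fired alert lists every order satisfying its condition. Alerts are
#' emitted in the fixed order mild, moderate, severe, pain, PCA. Order
#' linking information is deliberately ignored here (the live feed carried
#' none); it is read only by the appropriateness classifier.
#'
#' @param orders An [order_feed()] data.frame, all rows one patient.
#' @param t Evaluation timestamp.
#' @param bundle_version 1 or 2 (default 2, the current bundle).
#' @param rules Indication parse-rule table.
#' @return An alert-log data.frame: \code{rule_name}, \code{patient_id},
#'   \code{fired_at}, \code{triggering_order_ids} (semicolon-joined),
#'   \code{bundle_version}.
#' @export
detect_duplicates <- function(orders, t, bundle_version = 2L,
                              rules = default_parse_rules()) {
  stopifnot(bundle_version %in% c(1L, 2L))
  if (length(unique(orders$patient_id)) > 1) {
    stop("detect_duplicates() evaluates one patient at a time; got ",
         length(unique(orders$patient_id)), " patient ids")
  }
  t <- feed_time(t)
  if (nrow(orders) == 0) return(empty_alert_log())
  pid <- orders$patient_id[1]
  el <- eligible_orders(orders, t)
  if (nrow(el) < 2) return(empty_alert_log())
  cls <- classify_order(el, rules)
  rng <- matrix(NA_integer_, nrow(el), 2, dimnames = list(NULL, c("lower", "upper")))
  has_rng <- cls$kind %in% range_bearing_kinds()
  if (any(has_rng)) rng[has_rng, ] <- category_range(cls$kind[has_rng])

  alerts <- list()
  rule <- alert_rule_names()
  levels <- c(mild = "mild", moderate = "moderate", severe = "severe")
  for (lv in names(levels)) {
    lr <- category_range(lv)
    hit <- has_rng & rng[, "lower"] <= lr[, "upper"] & lr[, "lower"] <= rng[, "upper"]
    if (sum(hit) >= 2) {
      alerts[[length(alerts) + 1L]] <- data.frame(
        rule_name = rule[[lv]], patient_id = pid, fired_at = t,
        triggering_order_ids = paste(sort(el$order_id[hit]), collapse = ";"),
        bundle_version = as.integer(bundle_version), stringsAsFactors = FALSE)
    }
  }
  unclear <- cls$kind == "unspecified" & !el$is_pca &
    cls$min_bundle_version <= bundle_version
  if (any(unclear) && nrow(el) >= 2) {
    alerts[[length(alerts) + 1L]] <- data.frame(
      rule_name = rule[["pain"]], patient_id = pid, fired_at = t,
      triggering_order_ids = paste(sort(el$order_id), collapse = ";"),
      bundle_version = as.integer(bundle_version), stringsAsFactors = FALSE)
  }
  pca_ids <- sort(el$order_id[el$is_pca])
  partners <- el$order_id[!el$is_pca & el$is_prn & el$route == "intravenous"]
  if (length(pca_ids) >= 1 && length(partners) >= 1) {
    alerts[[length(alerts) + 1L]] <- data.frame(
      rule_name = rule[["pca"]], patient_id = pid, fired_at = t,
      triggering_order_ids = paste(c(pca_ids[1], sort(partners)), collapse = ";"),
      bundle_version = as.integer(bundle_version), stringsAsFactors = FALSE)
  }
  if (length(alerts) == 0) return(empty_alert_log())
  do.call(rbind, alerts)
}

#' Run the alert bundle over an order-event stream
#'
#' Event-driven evaluation: the bundle is evaluated at each order-start
#' event (the real-time proxy for order verification). A throttle suppresses
#' any alert whose scope key fired within the preceding window, limiting
#' alert fatigue to at most one activation per 24 hours per patient and rule.
#'
#' @param orders An [order_feed()] data.frame (any number of patients).
#' @param throttle_hours Throttle window in hours (default 24).
#' @param bundle_version 1 or 2.
#' @param throttle_scope \code{"rule"} (per patient and rule name, the
#'   default) or \code{"patient"} (one alert of any kind per patient per
#'   window, the patient-based review mode).
#' @param rules Indication parse-rule table.
#' @return Alert-log data.frame (see [detect_duplicates()]), sorted by
#'   \code{fired_at}, patient, and fixed rule order.
#' @export
stream_detect <- function(orders, throttle_hours = 24, bundle_version = 2L,
                          throttle_scope = c("rule", "patient"),
                          rules = default_parse_rules()) {
  throttle_scope <- match.arg(throttle_scope)
  stopifnot(throttle_hours > 0)
  validate_order_feed(orders)
  if (nrow(orders) == 0) return(empty_alert_log())

  events <- unique(orders[, c("patient_id", "start_time")])
  events <- events[order(events$start_time, events$patient_id), , drop = FALSE]
  window <- throttle_hours * 3600
  last_fired <- new.env(parent = emptyenv())
  out <- list()
  for (i in seq_len(nrow(events))) {
    pid <- events$patient_id[i]
    t <- events$start_time[i]
    porders <- orders[orders$patient_id == pid, , drop = FALSE]
    a <- detect_duplicates(porders, t, bundle_version, rules)
    if (nrow(a) == 0) next
    keep <- logical(nrow(a))
    for (j in seq_len(nrow(a))) {
      key <- if (throttle_scope == "rule") paste(pid, a$rule_name[j], sep = "\r")
             else pid
      prev <- last_fired[[key]]
      if (is.null(prev) || as.numeric(t) - prev >= window) {
        keep[j] <- TRUE
        last_fired[[key]] <- as.numeric(t)
      }
      if (throttle_scope == "patient" && keep[j]) break
    }
    if (any(keep)) out[[length(out) + 1L]] <- a[keep, , drop = FALSE]
  }
  if (length(out) == 0) return(empty_alert_log())
  log <- do.call(rbind, out)
  ro <- match(log$rule_name, alert_rule_names())
  log <- log[order(log$fired_at, log$patient_id, ro), , drop = FALSE]
  rownames(log) <- NULL
  log
}

#' Was a patient flagged by any alert during an interval?
#'
#' Patient-level test-positive state for validation: TRUE iff at least one
#' alert for the patient fired inside the closed interval.
#'
#' @param alert_log Alert-log data.frame.
#' @param patient_id Single patient id.
#' @param interval Length-2 timestamp vector \code{c(start, end)}, inclusive.
#' @return Logical scalar.
#' @export
patient_flagged <- function(alert_log, patient_id, interval) {
  interval <- feed_time(interval)
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  any(alert_log$patient_id == patient_id &
        alert_log$fired_at >= interval[1] &
        alert_log$fired_at <= interval[2])
}

#' Per-patient alert flags over an interval
#'
#' Vectorized [patient_flagged()] across a patient roster, aligned with
#' \code{patient_ids}; the usual input to [confusion_matrix()].
#'
#' @inheritParams patient_flagged
#' @param patient_ids Character vector of patient ids.
#' @return Named logical vector.
#' @export
alert_flags <- function(alert_log, patient_ids, interval) {
  interval <- feed_time(interval)
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  inwin <- alert_log$fired_at >= interval[1] & alert_log$fired_at <= interval[2]
  flagged <- unique(alert_log$patient_id[inwin])
  stats::setNames(patient_ids %in% flagged, patient_ids)
}
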