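# Appropriateness classification of a detected duplicate set and the matching
# pharmacist intervention, from three order attributes:
#   (1) same route and formulation (any pair),
#   (2) clear administration instructions (all orders),
#   (3) membership in a linked order group (all orders, same group).
# Category 1 (different formulation, clear, linked) is the only appropriate
# duplication; same route and formulation is category 5 regardless of the
# other attributes and calls for discontinuing all but one order.

interventions <- c("none", "clarify_instructions", "link_orders",
                   "clarify_and_link", "discontinue_all_but_one")

#' Default clear-instruction patterns
#'
#' Administration instructions are judged "clear" when they state a
#' condition for selecting this order over its alternatives. The default
#' patterns accept the conditional "give if ..." phrasing of the standard
#' instruction templates; the list is configurable because clarity
#' conventions differ between institutions.
#'
#' @return Character vector of case-insensitive regular expressions.
#' @export
default_clear_patterns <- function() {
  c("^\\s*give\\s+if\\b", "^\\s*use\\s+if\\b", "^\\s*administer\\s+if\\b",
    "\\bonly\\s+if\\b", "\\bfirst[- ]line\\b", "\\bsecond[- ]line\\b")
}

#' Standard administration-instruction templates
#'
#' The suggested instruction for each formulation/route, keyed
#' \code{"<route>.<formulation>"}.
#'
#' @return Named character vector.
#' @export
instruction_templates <- function() {
  c("oral.tablet" = "Give if patient can receive oral tablet medication.",
    "oral.solution" = "Give if patient cannot receive oral tablet medication but can receive oral solution medication.",
    "intravenous.injection" = "Give if patient is not able to receive oral medication.")
}

#' Recommended administration instruction for an order lacking one
#'
#' Returns the standard template matching the order's route and formulation;
#' unmapped combinations get a generic request for prescriber clarification.
#'
#' @param order One-row [order_feed()] data.frame (or a feed; vectorized).
#' @return Character vector of instruction texts.
#' @export
recommend_instruction <- function(order) {
  key <- paste(order$route, order$formulation, sep = ".")
  tpl <- instruction_templates()[key]
  unname(ifelse(is.na(tpl),
                "Clarify intended use with the prescriber and document an administration instruction.",
                tpl))
}

orders_clear <- function(orders, clear_patterns) {
  one <- function(s) {
    nzchar(trimws(s)) &&
      any(vapply(clear_patterns, grepl, logical(1), x = s,
                 ignore.case = TRUE, perl = TRUE))
  }
  vapply(orders$admin_instructions, one, logical(1), USE.NAMES = FALSE)
}

#' Assess a detected duplicate set
#'
#' Maps the three order attributes onto the five-category appropriateness
#' schema and its intervention:
#' \tabular{llll}{
#'   category \tab attributes (same r+f / clear / linked) \tab appropriate \tab intervention \cr
#'   1 \tab no / yes / yes \tab yes \tab none \cr
#'   2 \tab no / no / yes \tab no \tab clarify_instructions \cr
#'   3 \tab no / yes / no \tab no \tab link_orders \cr
#'   4 \tab no / no / no \tab no \tab clarify_and_link \cr
#'   5 \tab yes / any / any \tab no \tab discontinue_all_but_one \cr
#' }
#' "Same route and formulation" is evaluated pairwise: a set is category 5 if
#' any pair shares both tokens. "Clear" requires every order's instructions
#' to match a clear-instruction pattern. "Linked" requires all orders to
#' share one present \code{linked_group_id}. Linking is read here, at the
#' chart-review layer, and never by the detector, whose live feed carries no
#' linking information.
#'
#' @param dup_orders An [order_feed()] data.frame of \eqn{\ge 2} co-active
#'   orders for one patient, already judged duplicative.
#' @param clear_patterns See [default_clear_patterns()].
#' @return A \code{duplicate_assessment} list: \code{category},
#'   \code{same_route_and_formulation}, \code{clear_instructions},
#'   \code{linked}, \code{appropriate}, \code{intervention}.
#' @export
assess_duplicates <- function(dup_orders,
                              clear_patterns = default_clear_patterns()) {
  if (nrow(dup_orders) < 2) {
    stop("assess_duplicates() requires at least 2 orders; got ",
         nrow(dup_orders))
  }
  if (length(unique(dup_orders$patient_id)) != 1) {
    stop("assess_duplicates() requires orders from a single patient")
  }
  pairs <- utils::combn(nrow(dup_orders), 2)
  same_rf <- any(apply(pairs, 2, function(ix) {
    dup_orders$route[ix[1]] == dup_orders$route[ix[2]] &&
      dup_orders$formulation[ix[1]] == dup_orders$formulation[ix[2]]
  }))
  clear <- all(orders_clear(dup_orders, clear_patterns))
  lg <- dup_orders$linked_group_id
  linked <- !anyNA(lg) && length(unique(lg)) == 1L
  if (same_rf) {
    category <- 5L
  } else if (clear && linked) {
    category <- 1L
  } else if (!clear && linked) {
    category <- 2L
  } else if (clear && !linked) {
    category <- 3L
  } else {
    category <- 4L
  }
  structure(
    list(category = category,
         same_route_and_formulation = same_rf,
         clear_instructions = clear,
         linked = linked,
         appropriate = category == 1L,
         intervention = interventions[category]),
    class = "duplicate_assessment")
}

#' @export
print.duplicate_assessment <- function(x, ...) {
  cat(sprintf(
    "Duplicate assessment: category %d (%s)\n  same route+formulation: %s | clear instructions: %s | linked: %s\n  intervention: %s\n",
    x$category, if (x$appropriate) "appropriate" else "inappropriate",
    x$same_route_and_formulation, x$clear_instructions, x$linked,
    x$intervention))
  invisible(x)
}

#' Rank category-5 duplicate orders for discontinuation
#'
#' Orders the candidates by discontinuation preference: older start date
#' first, ties broken by lexicographic \code{order_id}. Reason codes beyond
#' \code{older_start_date} are emitted only when the corresponding optional
#' feed columns are present: \code{last_admin_time} (no administration within
#' 24 hours of \code{at}, or never, gives \code{no_recent_administration}),
#' logical \code{adverse_event} (\code{documented_adverse_event}), and
#' \code{order_set_id} (absent id gives \code{no_associated_order_set}).
#'
#' @param dup_orders The category-5 duplicate set ([order_feed()] rows).
#' @param at Reference time for administration recency (default: latest
#'   start in the set).
#' @return data.frame \code{order_id}, \code{rank}, \code{reasons}
#'   (semicolon-joined codes; \code{tie_break_order_id} when nothing else
#'   distinguishes the top candidate).
#' @export
discontinuation_rationale <- function(dup_orders, at = NULL) {
  if (nrow(dup_orders) < 1) stop("no candidate orders")
  if (is.null(at)) at <- max(dup_orders$start_time)
  at <- feed_time(at)
  o <- order(dup_orders$start_time, dup_orders$order_id)
  ranked <- dup_orders[o, , drop = FALSE]
  reasons <- lapply(seq_len(nrow(ranked)), function(i) {
    r <- character()
    if (nrow(ranked) > 1 && ranked$start_time[i] < max(ranked$start_time)) {
      r <- c(r, "older_start_date")
    }
    if ("last_admin_time" %in% names(ranked)) {
      la <- ranked$last_admin_time[i]
      if (is.na(la) || as.numeric(at) - as.numeric(feed_time(la)) > 24 * 3600) {
        r <- c(r, "no_recent_administration")
      }
    }
    if ("adverse_event" %in% names(ranked) && isTRUE(ranked$adverse_event[i])) {
      r <- c(r, "documented_adverse_event")
    }
    if ("order_set_id" %in% names(ranked) && is.na(ranked$order_set_id[i])) {
      r <- c(r, "no_associated_order_set")
    }
    if (length(r) == 0) r <- "tie_break_order_id"
    paste(r, collapse = ";")
  })
  data.frame(order_id = ranked$order_id, rank = seq_len(nrow(ranked)),
             reasons = unlist(reasons), stringsAsFactors = FALSE)
}

#' Assess every alert in a log against its triggering orders
#'
#' Convenience wrapper joining an alert log back to the feed and running
#' [assess_duplicates()] per alert; the machine-readable assessment report.
#'
#' @param alert_log Alert-log data.frame from [stream_detect()].
#' @param orders The [order_feed()] the log was computed from.
#' @param clear_patterns See [default_clear_patterns()].
#' @return data.frame: \code{patient_id}, \code{rule_name}, \code{fired_at},
#'   \code{order_ids}, \code{category}, \code{appropriate},
#'   \code{intervention}.
#' @export
assess_alerts <- function(alert_log, orders,
                          clear_patterns = default_clear_patterns()) {
  rows <- lapply(seq_len(nrow(alert_log)), function(i) {
    ids <- strsplit(alert_log$triggering_order_ids[i], ";", fixed = TRUE)[[1]]
    a <- assess_duplicates(orders[orders$order_id %in% ids, , drop = FALSE],
                           clear_patterns)
    data.frame(patient_id = alert_log$patient_id[i],
               rule_name = alert_log$rule_name[i],
               fired_at = alert_log$fired_at[i],
               order_ids = alert_log$triggering_order_ids[i],
               category = a$category, appropriate = a$appropriate,
               intervention = a$intervention, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(), rule_name = character(),
                      fired_at = as.POSIXct(character(), tz = "UTC"),
                      order_ids = character(), category = integer(),
                      appropriate = logical(), intervention = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
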