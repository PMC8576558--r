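# Readers and writers for the order-feed dialects (CSV, JSON-lines, and a
# minimal pipe-delimited HL7-v2-like pharmacy-order format) and for alert
# logs, labels, and validation reports. Round-trip fidelity: for any valid
# feed, read(write(x)) == x in CSV and JSONL; the HL7-lite reader yields the
# same feed as the CSV reader for equivalent content.

#' Default opioid formulary
#'
#' Drug-name substrings used to resolve \code{is_opioid} when a feed does not
#' carry the flag; matching is case-insensitive on \code{drug_name}.
#'
#' @return Character vector of opioid names.
#' @export
default_opioid_formulary <- function() {
  c("tramadol", "codeine", "hydrocodone", "oxycodone", "hydromorphone",
    "morphine", "fentanyl")
}

resolve_is_opioid <- function(drug_name, formulary) {
  pat <- paste(formulary, collapse = "|")
  grepl(pat, drug_name, ignore.case = TRUE)
}

feed_to_flat <- function(orders) {
  flat <- as.data.frame(orders)
  flat$start_time <- format_feed_time(flat$start_time)
  flat$end_time <- format_feed_time(flat$end_time)
  flat
}

#' Write an order feed
#'
#' @param orders An [order_feed()] data.frame.
#' @param path Output file.
#' @param format \code{"csv"} or \code{"jsonl"} (one JSON object per line,
#'   field names identical to the CSV header; absent values are null).
#' @return \code{path}, invisibly.
#' @export
write_order_feed <- function(orders, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  flat <- feed_to_flat(orders)
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(flat))) {
      rec <- as.list(flat[i, , drop = FALSE])
      rec$end_time <- if (rec$end_time == "") NULL else rec$end_time
      if (is.na(rec$linked_group_id)) rec$linked_group_id <- NULL
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    }
  }
  invisible(path)
}

#' Read an order feed
#'
#' Parses and validates a feed file. Malformed rows (missing identifiers,
#' unparseable start time, end time before start time) are rejected and
#' reported with their line numbers via a warning (or an error when
#' \code{strict = TRUE}). \code{is_opioid}, when absent, is resolved against
#' the opioid formulary. An empty file yields an empty feed with a warning.
#'
#' @param path Input file.
#' @param format \code{"csv"}, \code{"jsonl"}, or \code{"hl7lite"}.
#' @param formulary See [default_opioid_formulary()].
#' @param strict Error (rather than warn) on malformed rows.
#' @return An [order_feed()] data.frame.
#' @export
read_order_feed <- function(path, format = c("csv", "jsonl", "hl7lite"),
                            formulary = default_opioid_formulary(),
                            strict = FALSE) {
  format <- match.arg(format)
  if (format == "hl7lite") return(read_hl7lite(path, formulary, strict))
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  } else {
    txt <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(txt))
    recs <- lapply(txt[keep], function(s) {
      r <- jsonlite::fromJSON(s)
      r[vapply(r, is.null, logical(1))] <- NA
      lapply(r, as.character)
    })
    lines <- which(keep)
    raw <- if (length(recs)) {
      nm <- unique(unlist(lapply(recs, names)))
      as.data.frame(do.call(rbind, lapply(recs, function(r) {
        unlist(r[nm])[nm]
      })), stringsAsFactors = FALSE, col.names = nm) |>
        stats::setNames(nm)
    } else data.frame()
  }
  if (nrow(raw) == 0) {
    warning("empty order feed: ", path)
    return(order_feed(data.frame(order_id = character(),
                                 patient_id = character(),
                                 drug_name = character(),
                                 start_time = character(),
                                 stringsAsFactors = FALSE)))
  }
  finalize_feed(raw, lines, formulary, strict, path)
}

finalize_feed <- function(raw, lines, formulary, strict, path) {
  get <- function(col) if (col %in% names(raw)) raw[[col]] else NA_character_
  start_parsed <- suppressWarnings(
    as.numeric(feed_time(ifelse(is.na(get("start_time")) |
                                  get("start_time") == "",
                                "bad", get("start_time")))))
  end_raw <- get("end_time")
  end_parsed <- suppressWarnings(
    as.numeric(feed_time(ifelse(is.na(end_raw) | end_raw == "",
                                NA_character_, end_raw))))
  bad <- is.na(get("order_id")) | get("order_id") == "" |
    is.na(get("patient_id")) | get("patient_id") == "" |
    is.na(start_parsed) |
    (!is.na(end_parsed) & end_parsed < start_parsed)
  if (any(bad)) {
    msg <- paste0("rejected ", sum(bad), " malformed row(s) in ", path,
                  " at line(s): ", paste(lines[bad], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    return(order_feed(data.frame(order_id = character(),
                                 patient_id = character(),
                                 drug_name = character(),
                                 start_time = character(),
                                 stringsAsFactors = FALSE)))
  }
  if (!"is_opioid" %in% names(raw) || all(is.na(raw$is_opioid)) ||
      all(raw$is_opioid == "")) {
    raw$is_opioid <- resolve_is_opioid(raw$drug_name, formulary)
  } else {
    raw$is_opioid <- toupper(raw$is_opioid) %in% c("TRUE", "T", "1", "YES")
  }
  for (col in c("is_prn", "is_pca")) {
    if (col %in% names(raw)) {
      raw[[col]] <- toupper(as.character(raw[[col]])) %in%
        c("TRUE", "T", "1", "YES")
    }
  }
  if ("end_time" %in% names(raw)) {
    raw$end_time[!is.na(raw$end_time) & raw$end_time == ""] <- NA_character_
  }
  order_feed(raw)
}

## ---- HL7-lite --------------------------------------------------------------

#' Minimal HL7-v2-like pharmacy order reader and writer
#'
#' A documented pipe-delimited subset (not a certified HL7 v2
#' implementation). One message per order; segments:
#' \preformatted{
#' MSH|^~\&|<sending app>
#' PID|1|<patient_id>
#' ORC|NW|<order_id>|<linked_group_id>|<verify_location_class>|<start>|<end>
#' RXE|<drug_name>|<dose_text>|<route>|<formulation>|<is_opioid>|<is_prn>|<is_pca>
#' TQ1|<frequency_text>
#' NTE|PRN|<prn_indication_text>
#' NTE|ADMIN|<admin_instructions>
#' }
#' Timestamps are \code{YYYYMMDDHHMM}. PID and RXE are mandatory; a message
#' lacking either is rejected (with its starting line number). Booleans are
#' \code{1}/\code{0}; an empty \code{is_opioid} falls back to the formulary.
#'
#' @param path File path.
#' @param formulary See [default_opioid_formulary()].
#' @param strict Error rather than warn on rejected messages.
#' @return \code{read_hl7lite}: an [order_feed()].
#' @export
read_hl7lite <- function(path, formulary = default_opioid_formulary(),
                         strict = FALSE) {
  txt <- readLines(path, warn = FALSE)
  # message boundaries: an MSH line, or a PID line not preceded by MSH
  is_msh <- grepl("^MSH\\|", txt)
  is_pid <- grepl("^PID\\|", txt)
  starts <- which(is_msh | (is_pid & !c(FALSE, is_msh[-length(txt)])))
  if (length(starts) == 0) {
    warning("empty order feed: ", path)
    return(order_feed(data.frame(order_id = character(),
                                 patient_id = character(),
                                 drug_name = character(),
                                 start_time = character(),
                                 stringsAsFactors = FALSE)))
  }
  ends <- c(starts[-1] - 1L, length(txt))
  recs <- list()
  lines <- integer()
  bad_lines <- integer()
  hl7_time <- function(s) {
    if (is.na(s) || s == "") return(NA_character_)
    sprintf("%s-%s-%s %s:%s", substr(s, 1, 4), substr(s, 5, 6),
            substr(s, 7, 8), substr(s, 9, 10), substr(s, 11, 12))
  }
  for (k in seq_along(starts)) {
    seg <- txt[starts[k]:ends[k]]
    seg <- seg[nzchar(trimws(seg))]
    fld <- function(name, i, sub = NULL) {
      ln <- seg[grepl(paste0("^", name, "\\|"), seg)]
      if (!is.null(sub)) {
        ln <- ln[vapply(strsplit(ln, "|", fixed = TRUE),
                        function(p) length(p) >= 2 && p[2] == sub, logical(1))]
      }
      if (length(ln) == 0) return(NA_character_)
      parts <- strsplit(ln[1], "|", fixed = TRUE)[[1]]
      if (length(parts) < i) NA_character_ else parts[i]
    }
    pid <- fld("PID", 3)
    drug <- fld("RXE", 2)
    if (is.na(pid) || is.na(drug)) {
      bad_lines <- c(bad_lines, starts[k])
      next
    }
    recs[[length(recs) + 1L]] <- list(
      order_id = fld("ORC", 3), patient_id = pid, drug_name = drug,
      dose_text = fld("RXE", 3), route = fld("RXE", 4),
      formulation = fld("RXE", 5), is_opioid = fld("RXE", 6),
      is_prn = fld("RXE", 7), is_pca = fld("RXE", 8),
      frequency_text = fld("TQ1", 2),
      prn_indication_text = fld("NTE", 3, sub = "PRN"),
      admin_instructions = fld("NTE", 3, sub = "ADMIN"),
      start_time = hl7_time(fld("ORC", 6)), end_time = hl7_time(fld("ORC", 7)),
      verify_location_class = fld("ORC", 5),
      linked_group_id = fld("ORC", 4))
    lines <- c(lines, starts[k])
  }
  if (length(bad_lines)) {
    msg <- paste0("rejected ", length(bad_lines), " HL7-lite message(s) in ",
                  path, " lacking PID or RXE, at line(s): ",
                  paste(bad_lines, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  if (length(recs) == 0) {
    return(order_feed(data.frame(order_id = character(),
                                 patient_id = character(),
                                 drug_name = character(),
                                 start_time = character(),
                                 stringsAsFactors = FALSE)))
  }
  nm <- names(recs[[1]])
  raw <- as.data.frame(do.call(rbind, lapply(recs, function(r) {
    vapply(nm, function(f) {
      v <- r[[f]]
      if (is.na(v)) NA_character_ else v
    }, character(1))
  })), stringsAsFactors = FALSE)
  raw$prn_indication_text[is.na(raw$prn_indication_text)] <- ""
  raw$admin_instructions[is.na(raw$admin_instructions)] <- ""
  io <- raw$is_opioid
  raw$is_opioid <- NULL
  if (all(is.na(io) | io == "")) {
    raw$is_opioid <- resolve_is_opioid(raw$drug_name, formulary)
  } else {
    raw$is_opioid <- io %in% c("1", "TRUE", "T", "Y")
  }
  raw$is_prn[is.na(raw$is_prn)] <- "1"
  raw$is_pca[is.na(raw$is_pca)] <- "0"
  finalize_feed(raw, lines, formulary, strict, path)
}

#' @rdname read_hl7lite
#' @param orders An [order_feed()] data.frame.
#' @export
write_hl7lite <- function(orders, path) {
  con <- file(path, "w")
  on.exit(close(con))
  t_hl7 <- function(t) ifelse(is.na(t), "", format(t, "%Y%m%d%H%M", tz = "UTC"))
  b <- function(x) ifelse(x, "1", "0")
  for (i in seq_len(nrow(orders))) {
    o <- orders[i, ]
    writeLines(c(
      "MSH|^~\\&|opioidalerts",
      paste("PID", "1", o$patient_id, sep = "|"),
      paste("ORC", "NW", o$order_id,
            ifelse(is.na(o$linked_group_id), "", o$linked_group_id),
            o$verify_location_class, t_hl7(o$start_time), t_hl7(o$end_time),
            sep = "|"),
      paste("RXE", o$drug_name, o$dose_text, o$route, o$formulation,
            b(o$is_opioid), b(o$is_prn), b(o$is_pca), sep = "|"),
      paste("TQ1", o$frequency_text, sep = "|"),
      paste("NTE", "PRN", o$prn_indication_text, sep = "|"),
      paste("NTE", "ADMIN", o$admin_instructions, sep = "|")), con)
  }
  invisible(path)
}

## ---- alert logs and labels -------------------------------------------------

#' Read / write an alert log
#'
#' CSV columns (or identical JSONL fields): \code{rule_name},
#' \code{patient_id}, \code{fired_at}, \code{triggering_order_ids}
#' (semicolon-joined), \code{bundle_version}.
#'
#' @param alert_log Alert-log data.frame from [stream_detect()].
#' @param path File path.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @return \code{write_alert_log}: \code{path}, invisibly;
#'   \code{read_alert_log}: the alert-log data.frame.
#' @export
write_alert_log <- function(alert_log, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  flat <- alert_log
  flat$fired_at <- format_feed_time(flat$fired_at)
  if (format == "csv") {
    utils::write.csv(flat, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(flat))) {
      writeLines(jsonlite::toJSON(as.list(flat[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' @rdname write_alert_log
#' @export
read_alert_log <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    df <- if (length(txt)) {
      as.data.frame(do.call(rbind, lapply(txt, function(s) {
        unlist(jsonlite::fromJSON(s))
      })), stringsAsFactors = FALSE)
    } else data.frame()
  }
  if (nrow(df) == 0) return(empty_alert_log())
  df$fired_at <- feed_time(df$fired_at)
  df$bundle_version <- as.integer(df$bundle_version)
  df[, c("rule_name", "patient_id", "fired_at", "triggering_order_ids",
         "bundle_version")]
}

#' Read / write per-patient ground-truth labels
#'
#' @param labels Labels data.frame (see [generate_orders()]).
#' @param path File path.
#' @return \code{read_labels}: the labels data.frame.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$has_duplicate <- as.logical(df$has_duplicate)
  df
}
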