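# Core domain model: medication orders, pain categories, activity windows.
#
# An order feed is a plain data.frame with one row per order (column contract
# in `order_feed()`); all detection and classification functions operate on
# such data frames.

#' Pain category reference table
#'
#' The seven pain-indication categories used throughout the package, with the
#' inclusive 1-10 numeric-rating-scale score ranges for the five range-bearing
#' kinds. Patient-controlled analgesia (\code{pca}) and \code{unspecified}
#' carry no score range.
#'
#' @return A data.frame with columns \code{kind}, \code{lower}, \code{upper}
#'   (\code{NA} bounds for \code{pca} and \code{unspecified}).
#' @export
#' @examples
#' pain_categories()
pain_categories <- function() {
  data.frame(
    kind  = c("mild", "moderate", "severe", "mild_moderate",
              "moderate_severe", "pca", "unspecified"),
    lower = c(1L, 4L, 7L, 1L, 4L, NA_integer_, NA_integer_),
    upper = c(3L, 6L, 10L, 6L, 10L, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE
  )
}

pain_kinds <- function() pain_categories()$kind

range_bearing_kinds <- function() {
  pc <- pain_categories()
  pc$kind[!is.na(pc$lower)]
}

#' Score range of a pain category
#'
#' @param kind Character vector of category kinds (see [pain_categories()]).
#' @return A two-column matrix (\code{lower}, \code{upper}); \code{NA} rows
#'   for kinds without a range.
#' @export
category_range <- function(kind) {
  pc <- pain_categories()
  i <- match(kind, pc$kind)
  if (anyNA(i)) {
    stop("unknown pain category kind(s): ",
         paste(unique(kind[is.na(i)]), collapse = ", "))
  }
  cbind(lower = pc$lower[i], upper = pc$upper[i])
}

#' Do two pain categories cover a shared pain level?
#'
#' Two categories overlap when their inclusive integer score ranges intersect.
#' This, not kind equality, defines "same pain level": a combined 4-10 order
#' duplicates both a 4-6 and a 7-10 order.
#'
#' @param a,b Character vectors of range-bearing category kinds (recycled).
#' @return Logical vector.
#' @export
#' @examples
#' categories_overlap("moderate", "moderate_severe")  # TRUE
#' categories_overlap("mild", "severe")               # FALSE
categories_overlap <- function(a, b) {
  ra <- category_range(a)
  rb <- category_range(b)
  if (anyNA(ra) || anyNA(rb)) {
    stop("categories_overlap() requires range-bearing kinds; got a pca or ",
         "unspecified category")
  }
  unname(ra[, "lower"] <= rb[, "upper"] & rb[, "lower"] <= ra[, "upper"])
}

## ---- token normalization ---------------------------------------------------

route_tokens <- c("oral", "intravenous", "other")
formulation_tokens <- c("tablet", "solution", "injection", "patch", "other")
location_tokens <- c("acute_care", "icu", "operating_room", "procedural", "other")
censored_locations <- c("operating_room", "procedural")

norm_token <- function(x, map, tokens) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "other"
  mapped <- unname(map[x])
  out <- ifelse(is.na(mapped), x, mapped)
  out[!out %in% tokens] <- "other"
  unname(out)
}

#' @rdname normalize_tokens
#' @export
normalize_route <- function(x) {
  map <- c(po = "oral", oral = "oral", "by mouth" = "oral", "per os" = "oral",
           iv = "intravenous", intravenous = "intravenous",
           intravenously = "intravenous")
  norm_token(x, map, route_tokens)
}

#' @rdname normalize_tokens
#' @export
normalize_formulation <- function(x) {
  map <- c(tablet = "tablet", tab = "tablet", tabs = "tablet",
           capsule = "tablet", caplet = "tablet",
           solution = "solution", liquid = "solution", elixir = "solution",
           syrup = "solution", "oral solution" = "solution",
           injection = "injection", inj = "injection",
           injectable = "injection", infusion = "injection",
           patch = "patch", transdermal = "patch", "transdermal patch" = "patch")
  norm_token(x, map, formulation_tokens)
}

#' Normalize free-text route/formulation/location strings to closed token sets
#'
#' Unknown strings map to \code{"other"} so that rule matching is
#' deterministic at ingest.
#'
#' @param x Character vector.
#' @return Character vector of canonical tokens.
#' @name normalize_tokens
#' @export
normalize_location <- function(x) {
  map <- c(acute = "acute_care", "acute care" = "acute_care",
           acute_care = "acute_care", floor = "acute_care",
           ward = "acute_care",
           icu = "icu", "intensive care" = "icu", "intensive care unit" = "icu",
           or = "operating_room", "operating room" = "operating_room",
           operating_room = "operating_room",
           procedural = "procedural", procedure = "procedural",
           "procedural area" = "procedural", "cath lab" = "procedural",
           pacu = "procedural")
  norm_token(x, map, location_tokens)
}

## ---- timestamps ------------------------------------------------------------

#' Parse feed timestamps
#'
#' Timestamps are timezone-naive ISO 8601 at minute precision; one feed is
#' assumed to share one facility clock (represented internally as UTC).
#' Seconds, if present, are truncated.
#'
#' @param x Character vector (\code{"YYYY-MM-DD HH:MM"} or with a
#'   \code{"T"} separator), or a POSIXct.
#' @return POSIXct vector (UTC), floored to the minute.
#' @export
feed_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    t <- as.POSIXct(as.numeric(x), tz = "UTC", origin = "1970-01-01")
  } else {
    s <- gsub("T", " ", as.character(x), fixed = TRUE)
    t <- as.POSIXct(s, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  }
  floor_minute(t)
}

floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, tz = "UTC", origin = "1970-01-01")
}

format_feed_time <- function(t) {
  ifelse(is.na(t), "", format(t, "%Y-%m-%dT%H:%M", tz = "UTC"))
}

## ---- order feed constructor ------------------------------------------------

feed_columns <- c(
  "order_id", "patient_id", "drug_name", "is_opioid", "route", "formulation",
  "dose_text", "frequency_text", "is_prn", "is_pca", "prn_indication_text",
  "admin_instructions", "start_time", "end_time", "verify_location_class",
  "linked_group_id"
)

#' Construct a validated medication-order feed
#'
#' Normalizes route/formulation/location tokens, parses timestamps to minute
#' precision, and enforces the feed invariants: unique \code{order_id},
#' \code{start_time <= end_time} where an end is present, and PCA orders must
#' be intravenous. Missing optional columns are filled with defaults
#' (\code{end_time = NA} means open-ended; \code{linked_group_id = NA} means
#' unlinked).
#'
#' @param df A data.frame with (a subset of) the feed columns:
#'   \code{order_id}, \code{patient_id}, \code{drug_name}, \code{is_opioid},
#'   \code{route}, \code{formulation}, \code{dose_text},
#'   \code{frequency_text}, \code{is_prn}, \code{is_pca},
#'   \code{prn_indication_text}, \code{admin_instructions},
#'   \code{start_time}, \code{end_time}, \code{verify_location_class},
#'   \code{linked_group_id}.
#' @return The validated, normalized feed (class \code{order_feed},
#'   a data.frame).
#' @export
order_feed <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("order_id", "patient_id", "drug_name", "start_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("order feed missing required columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  def <- list(
    is_opioid = TRUE, route = "other", formulation = "other",
    dose_text = "", frequency_text = "", is_prn = TRUE, is_pca = FALSE,
    prn_indication_text = "", admin_instructions = "",
    end_time = NA_character_, verify_location_class = "acute_care",
    linked_group_id = NA_character_
  )
  for (col in names(def)) {
    if (!col %in% names(df)) df[[col]] <- rep(def[[col]], length.out = n)
  }
  out <- data.frame(
    order_id = as.character(df$order_id),
    patient_id = as.character(df$patient_id),
    drug_name = as.character(df$drug_name),
    is_opioid = as.logical(df$is_opioid),
    route = normalize_route(df$route),
    formulation = normalize_formulation(df$formulation),
    dose_text = as.character(df$dose_text),
    frequency_text = as.character(df$frequency_text),
    is_prn = as.logical(df$is_prn),
    is_pca = as.logical(df$is_pca),
    prn_indication_text = ifelse(is.na(df$prn_indication_text), "",
                                 as.character(df$prn_indication_text)),
    admin_instructions = ifelse(is.na(df$admin_instructions), "",
                                as.character(df$admin_instructions)),
    start_time = feed_time(df$start_time),
    end_time = if (all(is.na(df$end_time))) {
      as.POSIXct(rep(NA_real_, n), tz = "UTC", origin = "1970-01-01")
    } else feed_time(df$end_time),
    verify_location_class = normalize_location(df$verify_location_class),
    linked_group_id = {
      lg <- as.character(df$linked_group_id)
      lg[!is.na(lg) & lg == ""] <- NA_character_
      lg
    },
    stringsAsFactors = FALSE
  )
  validate_order_feed(out)
  class(out) <- c("order_feed", "data.frame")
  out
}

validate_order_feed <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  dup <- df$order_id[duplicated(df$order_id)]
  if (length(dup)) stop("duplicate order_id in feed: ",
                        paste(unique(dup), collapse = ", "))
  if (anyNA(df$start_time)) stop("unparseable start_time in feed")
  bad <- !is.na(df$end_time) & df$end_time < df$start_time
  if (any(bad)) stop("end_time precedes start_time for order(s): ",
                     paste(df$order_id[bad], collapse = ", "))
  bad_pca <- df$is_pca & df$route != "intravenous"
  if (any(bad_pca)) stop("PCA orders must be intravenous: ",
                         paste(df$order_id[bad_pca], collapse = ", "))
  invisible(df)
}

#' Is an order active at a time point?
#'
#' Activity windows are half-open \code{[start_time, end_time)}: a
#' discontinued order stops counting exactly at its end timestamp. An absent
#' end time means the order is open-ended.
#'
#' @param orders An [order_feed()] data.frame.
#' @param t A single timestamp (POSIXct or parseable string).
#' @return Logical vector, one element per order.
#' @export
is_active <- function(orders, t) {
  t <- feed_time(t)
  stopifnot(length(t) == 1L)
  orders$start_time <= t & (is.na(orders$end_time) | t < orders$end_time)
}
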