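# Parsing free-text PRN indications into pain categories.
#
# Two mechanisms, in order of precedence:
#   1. numeric score-range extraction ("... (score 4-6)"): a printed range
#      beats any surrounding words;
#   2. a prioritized, case-insensitive word-pattern table (editable config).
# Everything else that is nonempty falls through to "unspecified", as does
# empty text. "breakthrough pain" and "any pain" are unclear-indication forms
# recognized as alert triggers only from rule-bundle version 2 onward.

#' Default indication parse rules
#'
#' A prioritized pattern table mapping free-text PRN indications to pain
#' category kinds. Patterns are case-insensitive regular expressions; the
#' first match (lowest priority number) wins. \code{min_bundle_version}
#' records the first alert-bundle version at which an unclear-indication form
#' is recognized as a trigger for the "Opioids PRN for pain" alert:
#' "breakthrough pain" and "any pain" entered the bundle at version 2.
#'
#' Numeric score ranges are extracted before this table is consulted (see
#' [parse_indication()]), so the table only needs word vocabulary.
#'
#' @return data.frame with columns \code{pattern}, \code{target_kind},
#'   \code{min_bundle_version}, \code{priority}.
#' @seealso [read_parse_rules()] to load a customized table.
#' @export
default_parse_rules <- function() {
  data.frame(
    pattern = c(
      "mild\\s*(to|and|-|/)\\s*moderate",
      "moderate\\s*(to|and|-|/)\\s*severe",
      "\\bmild\\b",
      "\\bmoderate\\b",
      "\\bsevere\\b",
      "breakthrough",
      "\\bany\\s+pain\\b",
      ".^"  # never matches; placeholder keeps the catch-all explicit below
    ),
    target_kind = c("mild_moderate", "moderate_severe", "mild", "moderate",
                    "severe", "unspecified", "unspecified", "unspecified"),
    min_bundle_version = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L),
    priority = 1:8,
    stringsAsFactors = FALSE
  )
}

#' Read / write a parse-rule table
#'
#' The config dialect is a CSV with columns \code{pattern} (case-insensitive
#' regular expression), \code{target_kind} (a [pain_categories()] kind),
#' \code{min_bundle_version} (integer), \code{priority} (integer; lower
#' matches first).
#'
#' @param path File path.
#' @return \code{read_parse_rules}: the validated rule table.
#' @export
read_parse_rules <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pattern", "target_kind", "min_bundle_version", "priority")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parse-rule config missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(df$target_kind, pain_kinds())
  if (length(bad)) stop("unknown target_kind in parse-rule config: ",
                        paste(bad, collapse = ", "))
  df[order(df$priority), , drop = FALSE]
}

#' @rdname read_parse_rules
#' @param rules A parse-rule data.frame.
#' @export
write_parse_rules <- function(rules, path) {
  utils::write.csv(rules, path, row.names = FALSE)
  invisible(path)
}

# Extract the first "a-b" integer range (optionally "score a-b", "a to b").
extract_score_range <- function(text) {
  m <- regmatches(text, regexpr("([0-9]+)\\s*(-|to|–)\\s*([0-9]+)", text,
                                ignore.case = TRUE))
  if (length(m) == 0) return(NULL)
  nums <- as.integer(regmatches(m, gregexpr("[0-9]+", m))[[1]])
  if (length(nums) != 2) return(NULL)
  nums
}

# Map an extracted range to a category kind: exact Table-range match first;
# otherwise the narrowest enclosing range-bearing category if unique,
# else unspecified.
range_to_kind <- function(lo, hi) {
  if (is.na(lo) || is.na(hi) || lo > hi || lo < 1 || hi > 10) {
    return("unspecified")
  }
  pc <- pain_categories()
  pc <- pc[!is.na(pc$lower), , drop = FALSE]
  exact <- pc$kind[pc$lower == lo & pc$upper == hi]
  if (length(exact) == 1) return(exact)
  enclosing <- pc[pc$lower <= lo & hi <= pc$upper, , drop = FALSE]
  if (nrow(enclosing) == 0) return("unspecified")
  width <- enclosing$upper - enclosing$lower
  narrowest <- enclosing$kind[width == min(width)]
  if (length(narrowest) == 1) narrowest else "unspecified"
}

#' Parse PRN indication text into pain categories
#'
#' Total function: every string (including empty) maps to exactly one
#' category kind. A numeric score range, when present and resolvable, takes
#' precedence over word labels; otherwise the first matching rule in
#' \code{rules} wins; pain text without a recognizable scale, empty text,
#' "breakthrough pain" and "any pain" all map to \code{unspecified}.
#'
#' @param text Character vector of indication strings.
#' @param rules Parse-rule table, default [default_parse_rules()].
#' @return \code{parse_indication}: character vector of category kinds.
#'   \code{parse_indication_details}: data.frame with \code{text},
#'   \code{kind}, and \code{min_bundle_version} (the bundle version from
#'   which the matched form counts as an unclear-indication alert trigger;
#'   1 for all explicit and plain-unclear forms).
#' @export
#' @examples
#' parse_indication("PRN for severe pain (score 7-10)")
#' parse_indication("breakthrough pain")
parse_indication <- function(text, rules = default_parse_rules()) {
  parse_indication_details(text, rules)$kind
}

#' @rdname parse_indication
#' @export
parse_indication_details <- function(text, rules = default_parse_rules()) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  rules <- rules[order(rules$priority), , drop = FALSE]
  one <- function(s) {
    rng <- extract_score_range(s)
    if (!is.null(rng)) {
      kind <- range_to_kind(rng[1], rng[2])
      if (kind != "unspecified") return(c(kind, "1"))
    }
    for (i in seq_len(nrow(rules))) {
      if (grepl(rules$pattern[i], s, ignore.case = TRUE, perl = TRUE)) {
        return(c(rules$target_kind[i],
                 as.character(rules$min_bundle_version[i])))
      }
    }
    c("unspecified", "1")
  }
  res <- vapply(text, one, character(2), USE.NAMES = FALSE)
  data.frame(text = text, kind = res[1, ],
             min_bundle_version = as.integer(res[2, ]),
             stringsAsFactors = FALSE)
}

#' Classify eligible orders into pain categories
#'
#' PCA orders are categorized \code{pca} regardless of indication text;
#' all other orders are classified from their PRN indication text.
#'
#' @param orders An [order_feed()] data.frame of opioid PRN/PCA orders.
#' @param rules Parse-rule table.
#' @return data.frame with \code{order_id}, \code{kind},
#'   \code{min_bundle_version}.
#' @export
classify_order <- function(orders, rules = default_parse_rules()) {
  ok <- orders$is_opioid & (orders$is_prn | orders$is_pca)
  if (!all(ok)) {
    stop("classify_order() requires opioid PRN or PCA orders; offending ",
         "order(s): ", paste(orders$order_id[!ok], collapse = ", "))
  }
  det <- parse_indication_details(orders$prn_indication_text, rules)
  det$kind[orders$is_pca] <- "pca"
  det$min_bundle_version[orders$is_pca] <- 1L
  data.frame(order_id = orders$order_id, kind = det$kind,
             min_bundle_version = det$min_bundle_version,
             stringsAsFactors = FALSE)
}
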