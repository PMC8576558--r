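# Shared fixtures and independent oracles.

T0 <- feed_time("2024-03-04 08:00")
hrs <- function(h) h * 3600

# one-row order data.frame with sensible defaults
mk_order <- function(order_id, patient_id = "P1", kind = "moderate",
                     drug_name = "tramadol 50 mg", route = NULL,
                     formulation = NULL, is_pca = FALSE,
                     indication = NULL, instructions = "",
                     start = T0, end = NA, location = "acute_care",
                     linked = NA_character_, is_opioid = TRUE,
                     is_prn = !is_pca) {
  if (is.null(route)) route <- if (is_pca) "intravenous" else "oral"
  if (is.null(formulation)) {
    formulation <- if (route == "intravenous") "injection" else "tablet"
  }
  if (is.null(indication)) {
    indication <- switch(kind,
      mild = "PRN for mild pain (score 1-3)",
      moderate = "PRN for moderate pain (score 4-6)",
      severe = "PRN for severe pain (score 7-10)",
      mild_moderate = "PRN for mild to moderate pain (score 1-6)",
      moderate_severe = "PRN for moderate to severe pain (score 4-10)",
      unspecified = "PRN for pain",
      breakthrough = "breakthrough pain",
      pca = "")
  }
  data.frame(order_id = order_id, patient_id = patient_id,
             drug_name = drug_name, is_opioid = is_opioid, route = route,
             formulation = formulation, dose_text = drug_name,
             frequency_text = "every 6 hours PRN", is_prn = is_prn,
             is_pca = is_pca, prn_indication_text = indication,
             admin_instructions = instructions,
             start_time = format(start, "%Y-%m-%d %H:%M", tz = "UTC"),
             end_time = if (length(end) == 1 && is.na(end)[1]) NA_character_
                        else format(end, "%Y-%m-%d %H:%M", tz = "UTC"),
             verify_location_class = location, linked_group_id = linked,
             stringsAsFactors = FALSE)
}

mk_feed <- function(...) order_feed(do.call(rbind, list(...)))

# ---- brute-force detection oracle -------------------------------------------
# Independent of the package's detector: enumerates all unordered order pairs
# and checks each of the five rule predicates directly. `kinds` carries the
# ground-truth category per order ("breakthrough" marks the v2-only unclear
# form), so no parsing is involved.

oracle_ranges <- list(mild = c(1, 3), moderate = c(4, 6), severe = c(7, 10),
                      mild_moderate = c(1, 6), moderate_severe = c(4, 10))

oracle_detect <- function(orders, kinds, t, bundle_version = 2) {
  active <- orders$start_time <= t &
    (is.na(orders$end_time) | t < orders$end_time)
  keep <- orders$is_opioid & (orders$is_prn | orders$is_pca) & active &
    !orders$verify_location_class %in% c("operating_room", "procedural")
  orders <- orders[keep, , drop = FALSE]
  kinds <- kinds[keep]
  kinds[orders$is_pca] <- "pca"
  n <- nrow(orders)
  fired <- character()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ki <- kinds[i]; kj <- kinds[j]
        for (lv in c("mild", "moderate", "severe")) {
          r <- oracle_ranges[[lv]]
          hit <- function(k) {
            !is.null(oracle_ranges[[k]]) &&
              max(oracle_ranges[[k]][1], r[1]) <= min(oracle_ranges[[k]][2], r[2])
          }
          if (ki %in% names(oracle_ranges) && kj %in% names(oracle_ranges) &&
              hit(ki) && hit(kj)) {
            fired <- c(fired, alert_rule_names()[[lv]])
          }
        }
        unclear <- function(k, pca) {
          !pca && (k == "unspecified" || (k == "breakthrough" && bundle_version >= 2))
        }
        if (unclear(ki, orders$is_pca[i]) || unclear(kj, orders$is_pca[j])) {
          fired <- c(fired, alert_rule_names()[["pain"]])
        }
        iv_partner <- function(m) {
          !orders$is_pca[m] && orders$is_prn[m] &&
            orders$route[m] == "intravenous"
        }
        if ((orders$is_pca[i] && iv_partner(j)) ||
            (orders$is_pca[j] && iv_partner(i))) {
          fired <- c(fired, alert_rule_names()[["pca"]])
        }
      }
    }
  }
  sort(unique(fired))
}

# random single-patient order set for property tests
rand_orders <- function(n, pid = "P1") {
  kinds <- sample(c(names(oracle_ranges), "unspecified", "breakthrough", "pca"),
                  n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    k <- kinds[i]
    pca <- k == "pca"
    start <- T0 + hrs(sample(-48:24, 1))
    end <- if (runif(1) < 0.3) start + hrs(sample(1:96, 1)) else NA
    mk_order(sprintf("O%02d", i), pid, kind = k, is_pca = pca,
             route = if (pca) "intravenous" else sample(c("oral", "intravenous"), 1),
             start = start, end = end,
             location = sample(c("acute_care", "acute_care", "icu",
                                 "operating_room", "procedural"), 1),
             is_opioid = runif(1) < 0.9)
  })
  feed <- order_feed(do.call(rbind, rows))
  # order_feed preserves row order, so kinds stay aligned
  list(orders = feed, kinds = kinds)
}

# ---- Clopper-Pearson oracle by bisection on binomial tail sums --------------
cp_oracle <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  upper_tail <- function(p) sum(dbinom(x:n, n, p))     # P(X >= x)
  lower_tail <- function(p) sum(dbinom(0:x, n, p))     # P(X <= x)
  bisect <- function(f, target, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bisect(upper_tail, alpha / 2, 0, 1)
  # lower_tail decreases in p, so bisect on its negation
  upper <- if (x == n) 1 else {
    bisect(function(p) -lower_tail(p), -alpha / 2, 0, 1)
  }
  c(lower = lower, upper = upper)
}

# duplicate pair with a chosen (same route+formulation, clear, linked) triple
dup_pair <- function(same_rf, clear, linked) {
  instr1 <- if (clear) "Give if patient can receive oral tablet medication." else ""
  instr2 <- if (clear) {
    if (same_rf) "Give if patient can receive oral tablet medication."
    else "Give if patient is not able to receive oral medication."
  } else ""
  lg <- if (linked) "G1" else NA_character_
  mk_feed(
    mk_order("O1", kind = "severe", route = "oral", formulation = "tablet",
             drug_name = "oxycodone 10 mg", instructions = instr1, linked = lg),
    mk_order("O2", kind = "severe",
             route = if (same_rf) "oral" else "intravenous",
             formulation = if (same_rf) "tablet" else "injection",
             drug_name = if (same_rf) "hydrocodone-acetaminophen 10-325 mg"
                         else "morphine 4 mg",
             instructions = instr2, linked = lg))
}
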