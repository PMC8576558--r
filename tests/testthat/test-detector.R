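test_that("explicit per-level duplicates fire their alert", {
  severe <- mk_feed(
    mk_order("O1", kind = "severe", drug_name = "hydromorphone 1 mg",
             route = "intravenous"),
    mk_order("O2", kind = "severe", drug_name = "fentanyl 25 mcg",
             route = "intravenous"))
  a <- detect_duplicates(severe, T0)
  expect_identical(a$rule_name, "Opioids PRN for severe pain")
  expect_identical(a$triggering_order_ids, "O1;O2")

  single <- mk_feed(mk_order("O1", kind = "moderate"))
  expect_identical(nrow(detect_duplicates(single, T0)), 0L)

  disjoint <- mk_feed(mk_order("O1", kind = "mild"),
                      mk_order("O2", kind = "severe"))
  expect_identical(nrow(detect_duplicates(disjoint, T0)), 0L)
})

test_that("combined score ranges duplicate each level they cover", {
  feed <- mk_feed(mk_order("O1", kind = "moderate_severe"),
                  mk_order("O2", kind = "severe"))
  a <- detect_duplicates(feed, T0)
  expect_identical(a$rule_name, "Opioids PRN for severe pain")
  feed2 <- mk_feed(mk_order("O1", kind = "moderate_severe"),
                   mk_order("O2", kind = "moderate"))
  expect_identical(detect_duplicates(feed2, T0)$rule_name,
                   "Opioids PRN for moderate pain")
})

test_that("unclear-indication and PCA implicit duplicates fire", {
  pain <- mk_feed(
    mk_order("O1", kind = "unspecified",
             drug_name = "hydrocodone-acetaminophen 10-325 mg"),
    mk_order("O2", kind = "severe", drug_name = "morphine 15 mg"))
  expect_identical(detect_duplicates(pain, T0)$rule_name,
                   "Opioids PRN for pain")

  pca <- mk_feed(
    mk_order("O1", kind = "pca", is_pca = TRUE, drug_name = "hydromorphone"),
    mk_order("O2", kind = "severe", route = "intravenous",
             drug_name = "morphine 2 mg"))
  expect_identical(detect_duplicates(pca, T0)$rule_name, "Opioid PRN PCA")

  # an oral partner does not fire the PCA rule
  pca_oral <- mk_feed(
    mk_order("O1", kind = "pca", is_pca = TRUE, drug_name = "hydromorphone"),
    mk_order("O2", kind = "severe", route = "oral",
             drug_name = "oxycodone 10 mg"))
  expect_identical(nrow(detect_duplicates(pca_oral, T0)), 0L)

  # a lone unclear order is not a duplicate
  lone <- mk_feed(mk_order("O1", kind = "unspecified"))
  expect_identical(nrow(detect_duplicates(lone, T0)), 0L)
})

test_that("operating-room/procedural verification censors orders", {
  feed <- mk_feed(
    mk_order("O1", kind = "severe", route = "intravenous"),
    mk_order("O2", kind = "severe", route = "intravenous",
             location = "operating_room"))
  expect_identical(nrow(detect_duplicates(feed, T0)), 0L)
  feed2 <- mk_feed(
    mk_order("O1", kind = "severe"),
    mk_order("O2", kind = "severe", location = "procedural"),
    mk_order("O3", kind = "severe"))
  a <- detect_duplicates(feed2, T0)
  expect_identical(a$triggering_order_ids, "O1;O3")
})

test_that("detection ignores order linking but enforces one patient", {
  linked <- mk_feed(
    mk_order("O1", kind = "severe", linked = "G1"),
    mk_order("O2", kind = "severe", linked = "G1"))
  unlinked <- mk_feed(
    mk_order("O1", kind = "severe"),
    mk_order("O2", kind = "severe"))
  expect_identical(detect_duplicates(linked, T0)$rule_name,
                   detect_duplicates(unlinked, T0)$rule_name)
  mixed <- rbind(mk_order("O1", patient_id = "P1"),
                 mk_order("O2", patient_id = "P2"))
  expect_error(detect_duplicates(order_feed(mixed), T0), "one patient")
})

test_that("detect_duplicates equals the brute-force pairwise oracle", {
  set.seed(202)
  for (rep in 1:300) {
    n <- sample(2:8, 1)
    bv <- sample(1:2, 1)
    ro <- rand_orders(n)
    t <- T0 + hrs(sample(-24:24, 1))
    got <- sort(unique(detect_duplicates(ro$orders, t, bundle_version = bv)$rule_name))
    want <- oracle_detect(ro$orders, ro$kinds, t, bundle_version = bv)
    expect_identical(got, want,
                     info = sprintf("rep %d (n=%d, bv=%d)", rep, n, bv))
  }
})

test_that("adding an order never removes an alert type (monotonicity)", {
  set.seed(303)
  for (rep in 1:100) {
    ro <- rand_orders(sample(2:7, 1))
    extra <- rand_orders(1)
    extra$orders$order_id <- "O99"
    before <- detect_duplicates(ro$orders, T0)$rule_name
    combined <- order_feed(rbind(as.data.frame(ro$orders),
                                 as.data.frame(extra$orders)))
    after <- detect_duplicates(combined, T0)$rule_name
    expect_true(all(before %in% after), info = paste("rep", rep))
  }
})

test_that("stream throttling allows at most one activation per rule per window", {
  feed <- mk_feed(
    mk_order("O1", kind = "severe", start = T0),
    mk_order("O2", kind = "severe", start = T0),
    mk_order("O3", kind = "severe", start = T0 + hrs(6)))
  log <- stream_detect(feed)
  expect_identical(nrow(log), 1L)
  expect_identical(log$fired_at, T0)

  # duplication persisting past the window re-alerts
  feed2 <- mk_feed(
    mk_order("O1", kind = "severe", start = T0),
    mk_order("O2", kind = "severe", start = T0),
    mk_order("O3", kind = "severe", start = T0 + hrs(26)))
  expect_identical(nrow(stream_detect(feed2)), 2L)

  # distinct rules are throttled independently under the default scope
  feed3 <- mk_feed(
    mk_order("O1", kind = "severe", start = T0),
    mk_order("O2", kind = "severe", start = T0),
    mk_order("O3", kind = "moderate", start = T0 + hrs(2)),
    mk_order("O4", kind = "moderate", start = T0 + hrs(2)))
  expect_identical(nrow(stream_detect(feed3)), 2L)
  # ...but not under the patient-based scope
  expect_identical(nrow(stream_detect(feed3, throttle_scope = "patient")), 1L)

  expect_identical(nrow(stream_detect(order_feed(
    mk_order("O1", is_opioid = FALSE)))), 0L)
})

test_that("bundle version 2 adds the breakthrough/any-pain triggers", {
  feed <- mk_feed(
    mk_order("O1", kind = "breakthrough"),
    mk_order("O2", kind = "severe"))
  expect_identical(nrow(stream_detect(feed, bundle_version = 1)), 0L)
  v2 <- stream_detect(feed, bundle_version = 2)
  expect_identical(v2$rule_name, "Opioids PRN for pain")
})

test_that("throttle property holds on randomized feeds", {
  set.seed(404)
  for (rep in 1:30) {
    rows <- lapply(1:12, function(i) {
      mk_order(sprintf("O%02d", i), patient_id = sample(c("P1", "P2"), 1),
               kind = sample(c("moderate", "severe", "unspecified"), 1),
               start = T0 + hrs(sample(0:72, 1)))
    })
    log <- stream_detect(order_feed(do.call(rbind, rows)))
    if (nrow(log) < 2) next
    by_key <- split(as.numeric(log$fired_at),
                    paste(log$patient_id, log$rule_name))
    for (times in by_key) {
      if (length(times) >= 2) {
        expect_true(min(diff(sort(times))) >= 24 * 3600)
      }
    }
  }
})

test_that("patient_flagged uses a closed interval", {
  feed <- mk_feed(mk_order("O1", kind = "severe", start = T0),
                  mk_order("O2", kind = "severe", start = T0))
  log <- stream_detect(feed)
  expect_true(patient_flagged(log, "P1", c(T0, T0 + hrs(24))))  # boundary start
  expect_true(patient_flagged(log, "P1", c(T0 - hrs(24), T0)))  # boundary end
  expect_false(patient_flagged(log, "P1", c(T0 + 60, T0 + hrs(24))))
  expect_false(patient_flagged(empty <- log[0, ], "P1", c(T0, T0 + hrs(24))))
  expect_false(patient_flagged(log, "P2", c(T0, T0 + hrs(24))))
})
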