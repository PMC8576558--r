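test_that("the 2x2x2 attribute space maps exhaustively onto categories 1-5", {
  expected <- function(same_rf, clear, linked) {
    if (same_rf) 5L
    else if (clear && linked) 1L
    else if (!clear && linked) 2L
    else if (clear && !linked) 3L
    else 4L
  }
  intervention <- c("none", "clarify_instructions", "link_orders",
                    "clarify_and_link", "discontinue_all_but_one")
  for (same_rf in c(FALSE, TRUE)) {
    for (clear in c(FALSE, TRUE)) {
      for (linked in c(FALSE, TRUE)) {
        a <- assess_duplicates(dup_pair(same_rf, clear, linked))
        want <- expected(same_rf, clear, linked)
        info <- sprintf("same_rf=%s clear=%s linked=%s", same_rf, clear, linked)
        expect_identical(a$category, want, info = info)
        expect_identical(a$intervention, intervention[want], info = info)
        expect_identical(a$appropriate, want == 1L, info = info)
      }
    }
  }
})

test_that("same route but different formulation is not category 5", {
  # oral tablet + oral solution with clear instructions and linking: appropriate
  a <- assess_duplicates(mk_feed(
    mk_order("O1", kind = "moderate", route = "oral", formulation = "tablet",
             instructions = "Give if patient can receive oral tablet medication.",
             linked = "G9"),
    mk_order("O2", kind = "moderate", route = "oral", formulation = "solution",
             drug_name = "oxycodone 5 mg",
             instructions = paste("Give if patient cannot receive oral tablet",
                                  "medication but can receive oral solution medication."),
             linked = "G9")))
  expect_identical(a$category, 1L)
  expect_true(a$appropriate)
})

test_that("any same-route-and-formulation pair forces category 5 in larger sets", {
  trio <- mk_feed(
    mk_order("O1", kind = "severe", route = "oral", formulation = "tablet",
             instructions = "Give if patient can receive oral tablet medication.",
             linked = "G1"),
    mk_order("O2", kind = "severe", route = "intravenous",
             formulation = "injection", drug_name = "morphine 4 mg",
             instructions = "Give if patient is not able to receive oral medication.",
             linked = "G1"),
    mk_order("O3", kind = "severe", route = "oral", formulation = "tablet",
             drug_name = "hydromorphone 2 mg",
             instructions = "Give if patient can receive oral tablet medication.",
             linked = "G1"))
  a <- assess_duplicates(trio)
  expect_identical(a$category, 5L)
  expect_identical(a$intervention, "discontinue_all_but_one")
})

test_that("assess_duplicates is permutation-invariant and needs two orders", {
  feed <- dup_pair(FALSE, TRUE, FALSE)
  rev_feed <- order_feed(as.data.frame(feed)[2:1, ])
  expect_identical(assess_duplicates(feed)$category,
                   assess_duplicates(rev_feed)$category)
  expect_error(assess_duplicates(feed[1, ]), "at least 2")
})

test_that("instruction templates are the standard texts, byte for byte", {
  tpl <- instruction_templates()
  expect_identical(unname(tpl["oral.tablet"]),
                   "Give if patient can receive oral tablet medication.")
  expect_identical(unname(tpl["oral.solution"]),
                   "Give if patient cannot receive oral tablet medication but can receive oral solution medication.")
  expect_identical(unname(tpl["intravenous.injection"]),
                   "Give if patient is not able to receive oral medication.")

  expect_identical(
    recommend_instruction(order_feed(mk_order("O1", route = "oral",
                                              formulation = "tablet"))),
    "Give if patient can receive oral tablet medication.")
  patch <- order_feed(mk_order("O2", route = "other", formulation = "patch",
                               drug_name = "fentanyl 25 mcg/hr"))
  expect_match(recommend_instruction(patch), "prescriber")
})

test_that("discontinuation ranking prefers older orders with deterministic ties", {
  pair <- mk_feed(
    mk_order("O2", kind = "moderate", start = T0 - 2 * 86400),
    mk_order("O1", kind = "moderate", start = T0))
  r <- discontinuation_rationale(pair)
  expect_identical(r$order_id, c("O2", "O1"))
  expect_match(r$reasons[1], "older_start_date")

  tie <- mk_feed(mk_order("OB", kind = "moderate", start = T0),
                 mk_order("OA", kind = "moderate", start = T0))
  rt <- discontinuation_rationale(tie)
  expect_identical(rt$order_id, c("OA", "OB"))
  expect_identical(rt$reasons[1], "tie_break_order_id")

  solo <- mk_feed(mk_order("O1", kind = "moderate", start = T0))
  rs <- discontinuation_rationale(solo)
  expect_identical(nrow(rs), 1L)
  expect_true(nzchar(rs$reasons))
})

test_that("optional chart attributes add reason codes", {
  pair <- as.data.frame(mk_feed(
    mk_order("O1", kind = "moderate", start = T0 - 3 * 86400),
    mk_order("O2", kind = "moderate", start = T0)))
  pair$last_admin_time <- c(NA, format(T0, "%Y-%m-%d %H:%M"))
  pair$adverse_event <- c(TRUE, FALSE)
  pair$order_set_id <- c(NA_character_, "OS7")
  r <- discontinuation_rationale(pair, at = T0)
  expect_identical(r$order_id[1], "O1")
  expect_match(r$reasons[1], "no_recent_administration")
  expect_match(r$reasons[1], "documented_adverse_event")
  expect_match(r$reasons[1], "no_associated_order_set")
  expect_match(r$reasons[1], "older_start_date")
})

test_that("assess_alerts joins a log back to its feed", {
  feed <- mk_feed(
    mk_order("O1", kind = "severe", route = "oral", formulation = "tablet"),
    mk_order("O2", kind = "severe", route = "oral", formulation = "tablet",
             drug_name = "hydromorphone 2 mg"))
  log <- stream_detect(feed)
  rep <- assess_alerts(log, feed)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$category, 5L)
  expect_identical(rep$intervention, "discontinue_all_but_one")
})
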