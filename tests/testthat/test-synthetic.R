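test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_patients = 60, seed = 21)
  a <- generate_orders(cfg)
  b <- generate_orders(cfg)
  expect_identical(a, b)
  c <- generate_orders(generator_config(n_patients = 60, seed = 22))
  expect_false(identical(a$orders, c$orders))
})

test_that("config validation rejects malformed inputs", {
  expect_error(generator_config(n_patients = 0), "n_patients")
  mix <- default_category_mix(); mix["moderate"] <- 0.6
  expect_error(generator_config(category_mix = mix), "summing to 1")
  expect_error(generator_config(duplicate_prevalence = 1.2), "prevalence")
  expect_error(generator_config(noise = list(parser_evading = -0.1,
                                             procedural_censor = 0,
                                             chart_only = 0,
                                             transient_fp = 0)),
               "noise")
})

test_that("zero prevalence and zero noise give an alert-free cohort", {
  sim <- generate_orders(generator_config(n_patients = 120,
                                          duplicate_prevalence = 0, seed = 4))
  expect_false(any(sim$labels$has_duplicate))
  log <- stream_detect(sim$orders, bundle_version = 2)
  expect_identical(nrow(log), 0L)
})

test_that("planted duplicate sets satisfy the rule predicate their label claims", {
  sim <- generate_orders(generator_config(n_patients = 150, seed = 31))
  pos <- sim$labels[sim$labels$has_duplicate, ]
  expect_gt(nrow(pos), 10)
  for (i in seq_len(nrow(pos))) {
    pid <- pos$patient_id[i]
    po <- sim$orders[sim$orders$patient_id == pid, , drop = FALSE]
    # the planted set is built first, so its co-active start is order -O01's
    t <- po$start_time[po$order_id == paste0(pid, "-O01")]
    fired <- detect_duplicates(po, t, bundle_version = 2)$rule_name
    want <- strsplit(pos$dup_kinds[i], ";", fixed = TRUE)[[1]]
    rule_of <- c(moderate = "Opioids PRN for moderate pain",
                 severe = "Opioids PRN for severe pain",
                 unspecified = "Opioids PRN for pain")
    expect_true(all(rule_of[want] %in% fired),
                info = paste(pid, pos$dup_kinds[i]))
  }
})

test_that("label prevalence matches the configured rate within sampling error", {
  sim <- generate_orders(generator_config(n_patients = 2000, seed = 3))
  prev <- mean(sim$labels$has_duplicate)
  se <- sqrt(0.17 * 0.83 / 2000)
  expect_lte(abs(prev - 0.17), 3 * se)
})

test_that("with no planted duplicates the order category mix is the configured mix", {
  sim <- generate_orders(generator_config(n_patients = 4500,
                                          duplicate_prevalence = 0, seed = 5))
  expect_gte(nrow(sim$orders), 5000)
  kinds <- classify_order(sim$orders)$kind
  obs <- table(factor(kinds, levels = names(default_category_mix())))
  p <- stats::chisq.test(obs, p = default_category_mix())$p.value
  expect_gt(p, 0.01)
})

test_that("noise-free detection is perfect; noise degrades it in the expected direction", {
  clean <- generate_orders(generator_config(n_patients = 400, seed = 11))
  log <- stream_detect(clean$orders, bundle_version = 1)
  fl <- alert_flags(log, clean$labels$patient_id, clean$window)
  cm <- confusion_matrix(fl, clean$labels$has_duplicate)
  perf <- performance(cm)
  expect_identical(perf$estimate[perf$metric == "sensitivity"], 1)
  expect_identical(perf$estimate[perf$metric == "specificity"], 1)

  noisy <- generate_orders(generator_config(
    n_patients = 600, seed = 11,
    noise = list(parser_evading = 1 / 34, procedural_censor = 1 / 34,
                 chart_only = 1 / 34, transient_fp = 7 / 167)))
  logn <- stream_detect(noisy$orders, bundle_version = 1)
  fln <- alert_flags(logn, noisy$labels$patient_id, noisy$window)
  cmn <- confusion_matrix(fln, noisy$labels$has_duplicate)
  # false negatives only from the FN noise modes, false positives only from
  # the transient mode
  expect_gt(cmn$fn, 0)
  expect_gt(cmn$fp, 0)
  fn_modes <- noisy$labels$noise_mode[!fln & noisy$labels$has_duplicate]
  expect_true(all(fn_modes %in% c("parser_evading", "procedural_censor",
                                  "chart_only")))
  fp_modes <- noisy$labels$noise_mode[fln & !noisy$labels$has_duplicate]
  expect_true(all(fp_modes == "transient_fp"))
})

test_that("the step-2 fixture reproduces its published design exactly", {
  fx <- make_step2_fixture()
  expect_identical(nrow(fx$labels), 201L)
  expect_identical(sum(fx$labels$has_duplicate), 34L)
  # duplicate type split 12 / 9 / 7 / 6
  tab <- table(fx$labels$dup_kinds[fx$labels$has_duplicate])
  expect_identical(as.integer(tab[c("moderate", "severe", "moderate;severe",
                                    "unspecified")]),
                   c(12L, 9L, 7L, 6L))
  # 241 active orders with the published category counts
  act <- fx$orders[is_active(fx$orders, fx$review_time), ]
  expect_identical(nrow(act), 241L)
  mix <- table(classify_order(act)$kind)
  expect_identical(as.integer(mix[c("mild", "moderate", "severe",
                                    "mild_moderate", "moderate_severe", "pca",
                                    "unspecified")]),
                   c(3L, 123L, 93L, 2L, 6L, 5L, 9L))
})

test_that("the fixture's engineered misses vanish under the right conditions", {
  fx <- make_step2_fixture()
  # bundle v2 recovers the breakthrough-pain false negative
  log2 <- stream_detect(fx$orders, bundle_version = 2)
  fl2 <- alert_flags(log2, fx$labels$patient_id, fx$window)
  cm2 <- confusion_matrix(fl2, fx$labels$has_duplicate)
  expect_identical(cm2$fn, 1L)
  pe <- fx$labels$patient_id[fx$labels$noise_mode == "parser_evading"]
  expect_true(fl2[[pe]])
})
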