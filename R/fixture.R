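# Deterministic 201-patient accuracy-evaluation fixture.
#
# The cohort reproduces, by construction, the published step-2 validation
# conditions: 241 active PRN/PCA opioid orders whose pain-category counts
# equal the published order mix (3 mild / 123 moderate / 93 severe /
# 2 mild-and-moderate / 6 moderate-and-severe / 5 PCA / 9 unspecified),
# 34 patients with true duplicate sets (12 moderate / 9 severe / 7 both
# levels / 6 unclear-indication), two engineered false negatives (one
# "breakthrough pain" indication invisible to rule-bundle version 1, one
# operating-room-verified order removed by censoring), and seven engineered
# false positives (transient duplicate pairs discontinued before chart
# review). Run through stream_detect(bundle_version = 1), the patient-level
# confusion matrix is exactly (tp, fp, fn, tn) = (32, 7, 2, 160).

fx_row <- function(pid, j, kind, start, end = NA, drug = NULL, route = NULL,
                   formulation = NULL, is_pca = FALSE, indication = NULL,
                   instructions = "", linked = NA_character_,
                   location = "acute_care") {
  if (is.null(route)) route <- if (is_pca || kind == "severe") "intravenous" else "oral"
  if (is.null(formulation)) {
    formulation <- if (route == "intravenous") "injection" else "tablet"
  }
  if (is.null(drug)) drug <- category_drugs(kind)[1]
  if (is.null(indication)) indication <- category_indication(kind)
  end_t <- if (length(end) == 1 && is.na(end)[1]) {
    as.POSIXct(NA_real_, tz = "UTC", origin = "1970-01-01")
  } else end
  list(order_id = sprintf("%s-O%02d", pid, j), patient_id = pid,
       drug_name = drug, is_opioid = TRUE, route = route,
       formulation = formulation, dose_text = drug,
       frequency_text = "every 4 hours PRN", is_prn = !is_pca,
       is_pca = is_pca, prn_indication_text = indication,
       admin_instructions = instructions, start_time = start,
       end_time = end_t, verify_location_class = location,
       linked_group_id = linked, kind = kind, chart_only = FALSE)
}

fx_label <- function(pid, has_dup, kinds = NA_character_,
                     category = NA_integer_, noise = "none", n_orders) {
  data.frame(patient_id = pid, has_duplicate = has_dup, dup_kinds = kinds,
             dup_category = category,
             dup_same_route_formulation = if (is.na(category)) NA else category == 5L,
             dup_clear_instructions = if (is.na(category)) NA else category %in% c(1L, 3L),
             dup_linked = if (is.na(category)) NA else category %in% c(1L, 2L),
             noise_mode = noise, n_orders = n_orders,
             stringsAsFactors = FALSE)
}

#' Deterministic step-2 style validation fixture
#'
#' Builds a fixed 201-patient, 5-day order feed with per-patient ground-truth
#' labels, engineered so that the shipped detector at
#' \code{bundle_version = 1} classifies patients into exactly 32 true
#' positives, 7 false positives, 2 false negatives, and 160 true negatives
#' against the labels (chart-review truth prevalence 34/201 = 17\%). The 241
#' orders active at \code{review_time} match the published order-level pain
#' category mix. The two false negatives arise from a "breakthrough pain"
#' indication (recognized only from bundle version 2) and from
#' operating-room censoring; the seven false positives are transient
#' duplicate pairs discontinued within an hour, before chart review.
#'
#' @param start_date Window start date (\code{"YYYY-MM-DD"}).
#' @return Same shape as [generate_orders()]: list with \code{orders},
#'   \code{labels}, \code{window}, \code{review_time}.
#' @export
#' @examples
#' fx <- make_step2_fixture()
#' log <- stream_detect(fx$orders, bundle_version = 1)
#' flags <- alert_flags(log, fx$labels$patient_id, fx$window)
#' confusion_matrix(flags, fx$labels$has_duplicate)
make_step2_fixture <- function(start_date = "2024-03-04") {
  ws <- feed_time(paste(start_date, "00:00"))
  we <- ws + 5 * 86400
  day8 <- function(k) ws + ((k - 1) %% 5) * 86400 + 8 * 3600  # 08:00, cycling days

  rows <- list()
  labs <- list()
  pid_n <- 0L
  next_pid <- function() {
    pid_n <<- pid_n + 1L
    sprintf("P%03d", pid_n)
  }

  ## -- 12 moderate duplicate pairs (attribute variety across categories 1-5)
  for (i in 1:12) {
    pid <- next_pid()
    t0 <- day8(i)
    cat5 <- i >= 7
    clear <- i %in% c(1:3, 5)
    linked <- i %in% c(1:4)
    category <- if (cat5) 5L else if (clear && linked) 1L else
      if (!clear && linked) 2L else if (clear && !linked) 3L else 4L
    lg <- if (linked) sprintf("G-%s", pid) else NA_character_
    f2 <- if (cat5) "tablet" else "solution"
    i1 <- if (clear) unname(instruction_templates()["oral.tablet"]) else ""
    i2 <- if (clear) unname(instruction_templates()["oral.solution"]) else ""
    if (cat5) i2 <- ""
    rows <- c(rows, list(
      fx_row(pid, 1, "moderate", t0, drug = "hydrocodone-acetaminophen 5-325 mg",
             route = "oral", formulation = "tablet", instructions = i1,
             linked = lg),
      fx_row(pid, 2, "moderate", t0, drug = "tramadol 50 mg", route = "oral",
             formulation = f2, instructions = i2, linked = lg)))
    labs <- c(labs, list(fx_label(pid, TRUE, "moderate", category,
                                  n_orders = 2L)))
  }

  ## -- 9 severe duplicate pairs; the 9th is censored (operating room)
  for (i in 1:9) {
    pid <- next_pid()
    t0 <- day8(i + 1)
    loc2 <- if (i == 9) "operating_room" else "acute_care"
    noise <- if (i == 9) "procedural_censor" else "none"
    rows <- c(rows, list(
      fx_row(pid, 1, "severe", t0, drug = "hydromorphone 1 mg"),
      fx_row(pid, 2, "severe", t0, drug = "fentanyl 25 mcg", location = loc2)))
    labs <- c(labs, list(fx_label(pid, TRUE, "severe", 5L, noise = noise,
                                  n_orders = 2L)))
  }

  ## -- 7 duplicate sets on both the moderate and severe levels
  for (i in 1:7) {
    pid <- next_pid()
    t0 <- day8(i + 2)
    rows <- c(rows, list(
      fx_row(pid, 1, "moderate", t0, drug = "hydrocodone-acetaminophen 5-325 mg"),
      fx_row(pid, 2, "moderate", t0, drug = "tramadol 50 mg"),
      fx_row(pid, 3, "severe", t0, drug = "hydromorphone 1 mg"),
      fx_row(pid, 4, "severe", t0, drug = "fentanyl 25 mcg")))
    labs <- c(labs, list(fx_label(pid, TRUE, "moderate;severe", 5L,
                                  n_orders = 4L)))
  }

  ## -- 6 unclear-indication duplicates; the 6th evades bundle version 1
  for (i in 1:6) {
    pid <- next_pid()
    t0 <- day8(i + 3)
    ind <- if (i == 6) "breakthrough pain" else "PRN for pain"
    noise <- if (i == 6) "parser_evading" else "none"
    rows <- c(rows, list(
      fx_row(pid, 1, "unspecified", t0,
             drug = "hydrocodone-acetaminophen 10-325 mg", route = "oral",
             formulation = "tablet", indication = ind),
      fx_row(pid, 2, "severe", t0, drug = "morphine 15 mg", route = "oral",
             formulation = "solution")))
    labs <- c(labs, list(fx_label(pid, TRUE, "unspecified", 4L, noise = noise,
                                  n_orders = 2L)))
  }

  ## -- 7 transient false-positive pairs (second order lived one hour)
  for (i in 1:7) {
    pid <- next_pid()
    t0 <- day8(i)
    rows <- c(rows, list(
      fx_row(pid, 1, "moderate", t0, drug = "hydrocodone-acetaminophen 5-325 mg"),
      fx_row(pid, 2, "moderate", t0 + 2 * 3600, end = t0 + 3 * 3600,
             drug = "tramadol 50 mg")))
    labs <- c(labs, list(fx_label(pid, FALSE, noise = "transient_fp",
                                  n_orders = 2L)))
  }

  ## -- 160 true negatives
  neg <- function(kinds, drugs = NULL, routes = NULL, forms = NULL) {
    pid <- next_pid()
    t0 <- day8(pid_n)
    for (k in seq_along(kinds)) {
      kd <- kinds[k]
      rows[[length(rows) + 1L]] <<- fx_row(
        pid, k, kd, t0 + (k - 1) * 1800,
        drug = if (!is.null(drugs)) drugs[k] else NULL,
        route = if (!is.null(routes)) routes[k] else NULL,
        formulation = if (!is.null(forms)) forms[k] else NULL,
        is_pca = kd == "pca")
    }
    labs[[length(labs) + 1L]] <<- fx_label(pid, FALSE, n_orders = length(kinds))
  }
  for (i in 1:3) neg(c("mild", "severe"))                     # disjoint levels
  for (i in 1:2) neg(c("mild_moderate", "severe"))            # 1-6 vs 7-10
  for (i in 1:6) neg("moderate_severe")
  for (i in 1:5) neg("pca")
  for (i in 1:3) neg("unspecified")
  for (i in 1:78) neg("moderate")
  for (i in 1:50) neg("severe")
  for (i in 1:13) {                                           # no opioid orders
    pid <- next_pid()
    labs[[length(labs) + 1L]] <- fx_label(pid, FALSE, n_orders = 0L)
  }

  labels <- do.call(rbind, labs)
  rownames(labels) <- NULL
  list(orders = rows_to_feed(rows), labels = labels, window = c(ws, we),
       review_time = we)
}
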