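# Seeded generator of labeled synthetic inpatient order streams, plus the
# deterministic 201-patient accuracy-evaluation fixture. The generator plants
# duplicate sets per patient at a configured prevalence and resolves
# *accidental* background conflicts by time-staggering (a conflicting later
# order starts only after the earlier one ends), so per-patient duplicate
# labels are exactly Bernoulli(duplicate_prevalence) and the marginal
# indication-category mix of background orders is exactly category_mix.

#' Default study-condition mixes for the generator
#'
#' The order-level pain-category mix and the duplicate-set type mix used as
#' [generator_config()] defaults.
#'
#' @return Named probability vector.
#' @export
default_category_mix <- function() {
  c(mild = 0.01, moderate = 0.51, severe = 0.39, mild_moderate = 0.01,
    moderate_severe = 0.02, pca = 0.02, unspecified = 0.04)
}

#' @rdname default_category_mix
#' @export
default_duplicate_type_mix <- function() {
  c(moderate = 0.35, severe = 0.26, both = 0.21, unspecified = 0.18)
}

#' Generator configuration
#'
#' Study-condition defaults: 201 patients carrying on average 1.2 active PRN
#' opioid orders over a 5-day observation window; the order-level pain
#' category mix (1% mild, 51% moderate, 39% severe, 1% mild-and-moderate,
#' 2% moderate-and-severe, 2% PCA, 4% unspecified); 17% of patients carrying
#' at least one duplicate set, split 35% moderate / 26% severe / 21% both
#' levels / 18% unclear-indication. Noise rates (all default 0) control the
#' documented false-negative and false-positive mechanisms:
#' \code{parser_evading} (a planted duplicate order's indication is rewritten
#' to "breakthrough pain"/"any pain", invisible to rule-bundle version 1),
#' \code{procedural_censor} (one planted order verified in a procedural
#' area, so it is censored), \code{chart_only} (one planted order visible to
#' chart review but absent from the feed), and \code{transient_fp} (a
#' non-duplicate patient gets a short-lived duplicate pair that fires an
#' alert but is resolved before chart review).
#'
#' @param n_patients Number of patients.
#' @param mean_orders_per_patient Poisson mean of background orders.
#' @param category_mix Probability vector over [pain_categories()] kinds.
#' @param duplicate_prevalence Probability a patient carries a planted
#'   duplicate set.
#' @param duplicate_type_mix Probabilities over duplicate set types
#'   \code{moderate}, \code{severe}, \code{both}, \code{unspecified}.
#' @param noise Named list of the four noise probabilities.
#' @param window_days Observation window length in days.
#' @param start_date Window start date (\code{"YYYY-MM-DD"}).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return A validated \code{generator_config} list.
#' @export
generator_config <- function(n_patients = 201,
                             mean_orders_per_patient = 1.2,
                             category_mix = default_category_mix(),
                             duplicate_prevalence = 0.17,
                             duplicate_type_mix = default_duplicate_type_mix(),
                             noise = list(parser_evading = 0,
                                          procedural_censor = 0,
                                          chart_only = 0,
                                          transient_fp = 0),
                             window_days = 5,
                             start_date = "2024-03-04",
                             seed = NULL) {
  cfg <- list(n_patients = n_patients,
              mean_orders_per_patient = mean_orders_per_patient,
              category_mix = category_mix,
              duplicate_prevalence = duplicate_prevalence,
              duplicate_type_mix = duplicate_type_mix,
              noise = noise, window_days = window_days,
              start_date = start_date, seed = seed)
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$mean_orders_per_patient >= 0,
            cfg$window_days >= 1)
  if (!setequal(names(cfg$category_mix), pain_kinds())) {
    stop("category_mix must name all pain category kinds")
  }
  if (abs(sum(cfg$category_mix) - 1) > 1e-9 || any(cfg$category_mix < 0)) {
    stop("category_mix must be a probability vector summing to 1")
  }
  if (!setequal(names(cfg$duplicate_type_mix),
                c("moderate", "severe", "both", "unspecified"))) {
    stop("duplicate_type_mix must name moderate, severe, both, unspecified")
  }
  if (abs(sum(cfg$duplicate_type_mix) - 1) > 1e-9 ||
      any(cfg$duplicate_type_mix < 0)) {
    stop("duplicate_type_mix must be a probability vector summing to 1")
  }
  if (cfg$duplicate_prevalence < 0 || cfg$duplicate_prevalence > 1) {
    stop("duplicate_prevalence must be in [0, 1]")
  }
  nz <- c("parser_evading", "procedural_censor", "chart_only", "transient_fp")
  if (!all(nz %in% names(cfg$noise))) {
    stop("noise must name ", paste(nz, collapse = ", "))
  }
  nv <- unlist(cfg$noise[nz])
  if (any(nv < 0) || any(nv > 1)) stop("noise rates must lie in [0, 1]")
  fn_total <- sum(nv[c("parser_evading", "procedural_censor", "chart_only")])
  if (fn_total > 1) stop("false-negative noise rates must sum to <= 1")
  invisible(cfg)
}

## ---- order construction vocabulary ----------------------------------------

category_drugs <- function(kind) {
  switch(kind,
    mild = c("tramadol 50 mg", "acetaminophen-codeine 300-30 mg"),
    moderate = c("hydrocodone-acetaminophen 5-325 mg", "tramadol 50 mg"),
    severe = c("hydromorphone 1 mg", "fentanyl 25 mcg", "morphine 4 mg",
               "oxycodone 10 mg"),
    mild_moderate = "tramadol 50 mg",
    moderate_severe = "oxycodone 5 mg",
    unspecified = c("hydrocodone-acetaminophen 10-325 mg", "morphine 15 mg"),
    pca = c("hydromorphone", "morphine"))
}

category_indication <- function(kind) {
  switch(kind,
    mild = "PRN for mild pain (score 1-3)",
    moderate = "PRN for moderate pain (score 4-6)",
    severe = "PRN for severe pain (score 7-10)",
    mild_moderate = "PRN for mild to moderate pain (score 1-6)",
    moderate_severe = "PRN for moderate to severe pain (score 4-10)",
    unspecified = "PRN for pain",
    pca = "")
}

# conflict between two co-active orders under the alert-bundle predicates
kinds_conflict <- function(kind_a, pca_a, route_a, prn_a,
                           kind_b, pca_b, route_b, prn_b) {
  rb <- range_bearing_kinds()
  if (kind_a %in% rb && kind_b %in% rb &&
      categories_overlap(kind_a, kind_b)) return(TRUE)
  if (kind_a == "unspecified" || kind_b == "unspecified") return(TRUE)
  if (pca_a && !pca_b && route_b == "intravenous" && prn_b) return(TRUE)
  if (pca_b && !pca_a && route_a == "intravenous" && prn_a) return(TRUE)
  FALSE
}

## ---- the generator ---------------------------------------------------------

#' Generate a labeled synthetic order stream
#'
#' Emits a time-sorted order feed plus per-patient ground-truth labels.
#' Identical seeds give identical output. Background order categories are
#' i.i.d. draws from \code{category_mix}; a background order that would
#' accidentally duplicate a co-active order is time-staggered to start after
#' that order ends (sequential therapy), so with all noise rates at zero the
#' detector's alerts agree exactly with the labels.
#'
#' @param config A [generator_config()].
#' @return List: \code{orders} (an [order_feed()]), \code{labels}
#'   (data.frame: \code{patient_id}, \code{has_duplicate}, \code{dup_kinds},
#'   \code{dup_category}, \code{dup_same_route_formulation},
#'   \code{dup_clear_instructions}, \code{dup_linked}, \code{noise_mode},
#'   \code{n_orders}), \code{window} (length-2 POSIXct), \code{review_time}.
#' @export
generate_orders <- function(config = generator_config()) {
  validate_generator_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  ws <- feed_time(paste(config$start_date, "00:00"))
  we <- ws + config$window_days * 86400
  horizon <- we + 48 * 3600  # planted orders expire shortly after the window

  rows <- list()
  labs <- list()
  add_row <- function(pid, j, kind, start, end, drug = NULL, route = NULL,
                      formulation = NULL, is_pca = NULL, indication = NULL,
                      instructions = "", linked = NA_character_,
                      location = "acute_care") {
    if (is.null(drug)) drug <- sample(category_drugs(kind), 1)
    pca <- if (is.null(is_pca)) kind == "pca" else is_pca
    if (is.null(route)) route <- if (pca || kind == "severe") "intravenous" else "oral"
    if (is.null(formulation)) {
      formulation <- if (route == "intravenous") "injection" else "tablet"
    }
    if (is.null(indication)) indication <- category_indication(kind)
    list(order_id = sprintf("%s-O%02d", pid, j), patient_id = pid,
         drug_name = drug, is_opioid = TRUE, route = route,
         formulation = formulation, dose_text = drug,
         frequency_text = "every 4 hours PRN", is_prn = !pca, is_pca = pca,
         prn_indication_text = indication, admin_instructions = instructions,
         start_time = start, end_time = end,
         verify_location_class = location, linked_group_id = linked,
         kind = kind, chart_only = FALSE)
  }

  rand_start <- function() {
    floor_minute(ws + stats::runif(1, 0, (config$window_days - 1) * 86400))
  }

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    placed <- list()
    j <- 0L
    is_dup <- stats::runif(1) < config$duplicate_prevalence
    noise_mode <- "none"
    dup_kinds <- NA_character_
    dup_cat <- NA_integer_
    same_rf <- NA; clear <- NA; linked <- NA

    if (is_dup) {
      type <- sample(names(config$duplicate_type_mix), 1,
                     prob = config$duplicate_type_mix)
      dup_kinds <- switch(type, moderate = "moderate", severe = "severe",
                          both = "moderate;severe", unspecified = "unspecified")
      same_rf <- stats::runif(1) < 0.55
      clear <- !same_rf && stats::runif(1) < 0.5
      linked <- !same_rf && stats::runif(1) < 0.3
      dup_cat <- if (same_rf) 5L else if (clear && linked) 1L else
        if (!clear && linked) 2L else if (clear && !linked) 3L else 4L
      t0 <- rand_start()
      lg <- if (linked) sprintf("G-%s", pid) else NA_character_
      set_kinds <- switch(type,
        moderate = c("moderate", "moderate"),
        severe = c("severe", "severe"),
        both = c("moderate", "moderate", "severe", "severe"),
        unspecified = c("unspecified",
                        sample(c("moderate", "severe"), 1)))
      for (k in seq_along(set_kinds)) {
        kd <- set_kinds[k]
        # realize the attribute triple: pair-mate formulations differ unless
        # same_rf; clear sets get the standard conditional instruction
        alt <- k %% 2 == 0 && !same_rf
        route <- if (kd == "severe" && !alt) "intravenous" else "oral"
        formulation <- if (route == "intravenous") "injection" else
          if (alt) "solution" else "tablet"
        instr <- if (isTRUE(clear)) {
          unname(recommend_instruction(
            data.frame(route = route, formulation = formulation)))
        } else ""
        j <- j + 1L
        placed[[length(placed) + 1L]] <- add_row(
          pid, j, kd, t0, horizon, route = route, formulation = formulation,
          instructions = instr, linked = lg)
      }
      if (type %in% c("moderate", "severe", "unspecified")) {
        u <- stats::runif(1)
        nz <- config$noise
        if (u < nz$parser_evading) {
          noise_mode <- "parser_evading"
          target <- if (type == "unspecified") 1L else 2L
          placed[[target]]$prn_indication_text <-
            sample(c("breakthrough pain", "any pain"), 1)
        } else if (u < nz$parser_evading + nz$procedural_censor) {
          noise_mode <- "procedural_censor"
          placed[[2]]$verify_location_class <- "procedural"
        } else if (u < nz$parser_evading + nz$procedural_censor + nz$chart_only) {
          noise_mode <- "chart_only"
          placed[[2]]$chart_only <- TRUE
        }
      }
    } else if (stats::runif(1) < config$noise$transient_fp) {
      # short-lived duplicate: fires in the feed, resolved before chart review
      noise_mode <- "transient_fp"
      t0 <- rand_start()
      j <- j + 1L
      placed[[length(placed) + 1L]] <- add_row(pid, j, "moderate", t0, horizon,
                                               route = "oral",
                                               formulation = "tablet")
      j <- j + 1L
      placed[[length(placed) + 1L]] <- add_row(
        pid, j, "moderate", floor_minute(t0 + 2 * 3600),
        floor_minute(t0 + 3 * 3600), route = "oral", formulation = "tablet")
    }

    n_bg <- stats::rpois(1, config$mean_orders_per_patient)
    if (n_bg > 0) {
      kinds <- sample(pain_kinds(), n_bg, replace = TRUE,
                      prob = config$category_mix[pain_kinds()])
      for (kd in kinds) {
        start <- rand_start()
        dur <- round(stats::runif(1, 24, 96)) * 3600
        pca <- kd == "pca"
        route <- if (pca || kd == "severe") "intravenous" else "oral"
        # stagger past any co-active conflicting order already placed
        repeat {
          end <- start + dur
          clash <- vapply(placed, function(p) {
            start < p$end_time && p$start_time < end &&
              kinds_conflict(kd, pca, route, !pca,
                             p$kind, p$is_pca, p$route, p$is_prn)
          }, logical(1))
          if (!any(clash)) break
          latest <- max(vapply(placed[clash], function(p)
            as.numeric(p$end_time), numeric(1)))
          start <- floor_minute(as.POSIXct(latest, tz = "UTC",
                                           origin = "1970-01-01") + 60)
        }
        j <- j + 1L
        placed[[length(placed) + 1L]] <- add_row(pid, j, kd, start, end,
                                                 route = route)
      }
    }

    rows <- c(rows, placed)
    labs[[i]] <- data.frame(
      patient_id = pid, has_duplicate = is_dup, dup_kinds = dup_kinds,
      dup_category = dup_cat, dup_same_route_formulation = same_rf,
      dup_clear_instructions = clear, dup_linked = linked,
      noise_mode = noise_mode, n_orders = length(placed),
      stringsAsFactors = FALSE)
  }

  labels <- do.call(rbind, labs)
  feed <- rows_to_feed(rows)
  list(orders = feed, labels = labels, window = c(ws, we), review_time = we)
}

rows_to_feed <- function(rows) {
  rows <- Filter(function(r) !isTRUE(r$chart_only), rows)
  if (length(rows) == 0) {
    df <- data.frame(order_id = character(), patient_id = character(),
                     drug_name = character(), start_time = character(),
                     stringsAsFactors = FALSE)
    return(order_feed(df))
  }
  chr <- function(f) vapply(rows, function(r) as.character(r[[f]]), character(1))
  lgl <- function(f) vapply(rows, function(r) as.logical(r[[f]]), logical(1))
  tim <- function(f) {
    as.POSIXct(vapply(rows, function(r) as.numeric(r[[f]]), numeric(1)),
               tz = "UTC", origin = "1970-01-01")
  }
  df <- data.frame(
    order_id = chr("order_id"), patient_id = chr("patient_id"),
    drug_name = chr("drug_name"), is_opioid = lgl("is_opioid"),
    route = chr("route"), formulation = chr("formulation"),
    dose_text = chr("dose_text"), frequency_text = chr("frequency_text"),
    is_prn = lgl("is_prn"), is_pca = lgl("is_pca"),
    prn_indication_text = chr("prn_indication_text"),
    admin_instructions = chr("admin_instructions"),
    start_time = tim("start_time"), end_time = tim("end_time"),
    verify_location_class = chr("verify_location_class"),
    linked_group_id = chr("linked_group_id"),
    stringsAsFactors = FALSE)
  df <- df[order(df$start_time, df$order_id), , drop = FALSE]
  rownames(df) <- NULL
  order_feed(df)
}
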