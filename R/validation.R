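# Patient-level diagnostic validation of the alert bundle against a
# chart-review reference standard: confusion matrix, the five performance
# metrics with Clopper-Pearson exact binomial intervals, and the saturated
# categorical regression used to summarize pharmacist time effort.

#' Patient-level confusion matrix
#'
#' Cross-tabulates the alert flag (test) against the chart-review reference
#' standard (truth), aligned by patient.
#'
#' @param alert_flags Logical vector: patient had at least one alert.
#' @param truth_flags Logical vector: chart review found duplicate orders.
#' @return A \code{confusion_matrix} list with counts \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}.
#' @export
confusion_matrix <- function(alert_flags, truth_flags) {
  if (length(alert_flags) != length(truth_flags)) {
    stop("alert_flags and truth_flags must be aligned, equal-length vectors")
  }
  alert_flags <- as.logical(alert_flags)
  truth_flags <- as.logical(truth_flags)
  if (anyNA(alert_flags) || anyNA(truth_flags)) stop("flags must not be NA")
  structure(list(tp = sum(alert_flags & truth_flags),
                 fp = sum(alert_flags & !truth_flags),
                 fn = sum(!alert_flags & truth_flags),
                 tn = sum(!alert_flags & !truth_flags)),
            class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn Nonnegative counts (alternative direct constructor).
#' @export
as_confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) == 0) stop("confusion matrix must contain at least one patient")
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("alert", "no alert"),
                              c("duplicates", "no duplicates")))
  print(m)
  invisible(x)
}

#' Round a proportion to integer percent, halves up
#'
#' Display rounding used in all human-readable output (R's \code{round()}
#' rounds halves to even, which is not the convention here).
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Integer percent(s).
#' @export
percent_round <- function(p) {
  stats::setNames(as.integer(floor(p * 100 + 0.5)), names(p))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval obtained by inverting binomial tail probabilities,
#' computed via beta quantiles. Conservative: coverage is at least the
#' nominal level. \code{sided = "two"} gives the usual two-sided interval;
#' \code{sided = "lower"} gives a one-sided lower bound at level
#' \code{confidence} with upper bound 1 (for \code{x = n} the closed form is
#' \eqn{(1-\mathrm{confidence})^{1/n}}).
#'
#' @param x Number of successes.
#' @param n Number of trials (\eqn{\ge 1}).
#' @param confidence Confidence level, default 0.95.
#' @param sided \code{"two"} or \code{"lower"} (one-sided lower bound).
#' @return Named numeric vector \code{c(lower, upper)} of proportions.
#' @export
#' @examples
#' exact_ci(34, 201)                      # 0.121 to 0.229
#' exact_ci(10, 10, 0.975, sided = "lower")  # lower = 0.025^(1/10)
exact_ci <- function(x, n, confidence = 0.95, sided = c("two", "lower")) {
  sided <- match.arg(sided)
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      x != floor(x) || n != floor(n) || n < 1 || x < 0 || x > n) {
    stop("exact_ci() requires integer counts with 0 <= x <= n and n >= 1")
  }
  stopifnot(confidence > 0, confidence < 1)
  alpha <- 1 - confidence
  if (sided == "two") {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  } else {
    lower <- if (x == 0) 0 else stats::qbeta(alpha, x, n - x + 1)
    upper <- 1
  }
  c(lower = lower, upper = upper)
}

#' Diagnostic performance of the alert bundle
#'
#' Sensitivity, specificity, positive and negative predictive value, and
#' accuracy from a patient-level confusion matrix, each with a two-sided
#' Clopper-Pearson exact interval. Raw proportions are retained alongside
#' half-up integer-percent display columns.
#'
#' @param cm A [confusion_matrix()].
#' @param confidence Confidence level, default 0.95.
#' @return A \code{performance_report} data.frame: \code{metric},
#'   \code{numerator}, \code{denominator}, \code{estimate}, \code{lower},
#'   \code{upper} (proportions), and \code{value_pct}, \code{lower_pct},
#'   \code{upper_pct} (integer percents).
#' @export
performance <- function(cm, confidence = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty confusion matrix")
  defs <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv         = c(cm$tp, cm$tp + cm$fp),
    npv         = c(cm$tn, cm$tn + cm$fn),
    accuracy    = c(cm$tp + cm$tn, total)
  )
  bad <- names(defs)[vapply(defs, function(d) d[2] == 0, logical(1))]
  if (length(bad)) {
    stop("metric undefined (zero denominator): ", paste(bad, collapse = ", "))
  }
  rows <- lapply(names(defs), function(m) {
    d <- defs[[m]]
    ci <- exact_ci(d[1], d[2], confidence)
    data.frame(metric = m, numerator = d[1], denominator = d[2],
               estimate = d[1] / d[2], lower = ci[["lower"]],
               upper = ci[["upper"]], stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$value_pct <- percent_round(rep$estimate)
  rep$lower_pct <- percent_round(rep$lower)
  rep$upper_pct <- percent_round(rep$upper)
  class(rep) <- c("performance_report", "data.frame")
  rep
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Alert bundle performance (patient level)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-11s %3d%%  (95%% CI %d%%-%d%%)  [%d/%d]\n",
                x$metric[i], x$value_pct[i], x$lower_pct[i], x$upper_pct[i],
                x$numerator[i], x$denominator[i]))
  }
  invisible(x)
}

#' Time effort by extent of action taken
#'
#' Saturated categorical linear regression of pharmacist review minutes on
#' mutually exclusive action categories (no intercept), so fitted means equal
#' per-category sample means; confidence intervals use the pooled residual
#' variance, as in an ordinary least-squares fit.
#'
#' @param records data.frame with columns \code{action_category} and
#'   \code{minutes}. Typical categories: \code{no_action},
#'   \code{discontinued}, \code{advanced_modification},
#'   \code{contacted_provider_or_nurse}.
#' @param confidence Confidence level, default 0.95.
#' @return data.frame: \code{category}, \code{n}, \code{mean}, \code{lower},
#'   \code{upper} (minutes).
#' @export
fit_time_effort <- function(records, confidence = 0.95) {
  stopifnot(is.data.frame(records),
            all(c("action_category", "minutes") %in% names(records)))
  if (nrow(records) == 0) stop("no time-effort records")
  if (anyNA(records$minutes) || anyNA(records$action_category)) {
    stop("time-effort records must not contain NA")
  }
  records$action_category <- factor(records$action_category)
  if (any(table(records$action_category) == 0)) stop("empty action category")
  lv <- levels(records$action_category)
  counts <- as.integer(table(records$action_category)[lv])
  if (nlevels(records$action_category) >= 2) {
    fit <- stats::lm(minutes ~ 0 + action_category, data = records)
    est <- unname(stats::coef(fit))
    se <- unname(summary(fit)$coefficients[, "Std. Error"])
    dfres <- stats::df.residual(fit)
  } else {
    # lm() cannot build a design matrix on a single-level factor; the
    # saturated model there is just the sample mean with its usual SE
    est <- mean(records$minutes)
    dfres <- nrow(records) - 1L
    s2 <- if (dfres >= 1) stats::var(records$minutes) else NA_real_
    se <- sqrt(s2 / nrow(records))
  }
  if (dfres < 1 && any(is.na(se) | se > 0)) {
    stop("need at least 2 records in at least one category for a CI")
  }
  se[is.nan(se)] <- 0  # zero residual variance: degenerate zero-width CI
  tcrit <- if (dfres >= 1) stats::qt(1 - (1 - confidence) / 2, dfres) else 0
  data.frame(category = lv, n = counts, mean = est,
             lower = est - tcrit * se, upper = est + tcrit * se,
             stringsAsFactors = FALSE)
}
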