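# ---------------------------------------------------------------------------
# Patient-level outcome pipeline: HbA1c change, treatment-target
# attainment, HbA1c banding, care-plan adherence.
#
# A cohort is three tables:
#   patients:     patient_id, diabetes_type (1 or 2), enrollment_date,
#                 followup_months
#   measurements: patient_id, parameter, date, value, target_value,
#                 target_direction ("at_most" or "at_least")
#   careplan:     patient_id, item, planned_per_year, performed
# ---------------------------------------------------------------------------

DAYS_PER_MONTH <- 30.4375
MATCH_WINDOW_DAYS <- 42 # +/- 6 weeks around a nominal timepoint

#' Construct a patient cohort object
#'
#' Bundles and validates the three patient-level tables. Analyzed patients
#' must have at least 6 months of follow-up; measurement dates must fall
#' within each patient's enrollment window; values must be positive.
#'
#' @param patients data frame with `patient_id`, `diabetes_type` (1 or 2),
#'   `enrollment_date` (Date or ISO string), `followup_months`.
#' @param measurements data frame with `patient_id`, `parameter`, `date`,
#'   `value`, `target_value`, `target_direction`.
#' @param careplan data frame with `patient_id`, `item`,
#'   `planned_per_year`, `performed`.
#' @return An object of class `patient_cohort`.
#' @export
patient_cohort <- function(patients, measurements, careplan) {
  .require_fields(patients, c("patient_id", "diabetes_type",
                              "enrollment_date", "followup_months"),
                  "patients")
  .require_fields(measurements, c("patient_id", "parameter", "date",
                                  "value", "target_value",
                                  "target_direction"), "measurements")
  .require_fields(careplan, c("patient_id", "item", "planned_per_year",
                              "performed"), "careplan")
  patients$enrollment_date <- as.Date(patients$enrollment_date)
  measurements$date <- as.Date(measurements$date)
  if (any(!patients$diabetes_type %in% c(1L, 2L))) {
    stop("diabetes_type must be 1 or 2", call. = FALSE)
  }
  if (any(patients$followup_months < 6)) {
    stop("analyzed patients must have at least 6 months of follow-up; got ",
         min(patients$followup_months), " months", call. = FALSE)
  }
  if (nrow(measurements) > 0L) {
    if (any(measurements$value <= 0)) {
      stop("measurement values must be positive", call. = FALSE)
    }
    enr <- patients$enrollment_date[
      match(measurements$patient_id, patients$patient_id)]
    fup <- patients$followup_months[
      match(measurements$patient_id, patients$patient_id)]
    if (anyNA(enr)) {
      stop("measurement for unknown patient_id", call. = FALSE)
    }
    off <- as.numeric(measurements$date - enr)
    if (any(off < -MATCH_WINDOW_DAYS |
            off > fup * DAYS_PER_MONTH + MATCH_WINDOW_DAYS)) {
      stop("measurement dates must fall within the enrollment window",
           call. = FALSE)
    }
  }
  structure(list(patients = patients, measurements = measurements,
                 careplan = careplan),
            class = "patient_cohort")
}

# value of `parameter` nearest the nominal timepoint (months after
# enrollment), NA when no measurement falls within +/- 6 weeks
.value_at <- function(cohort, parameter, at_months) {
  pts <- cohort$patients
  ms <- cohort$measurements[cohort$measurements$parameter == parameter, ,
                            drop = FALSE]
  pi <- match(ms$patient_id, pts$patient_id)
  dist <- abs(as.numeric(ms$date - pts$enrollment_date[pi]) -
                at_months * DAYS_PER_MONTH)
  rows <- split(seq_len(nrow(ms)), factor(pi, levels = seq_len(nrow(pts))))
  vapply(rows, function(r) {
    if (length(r) == 0L) return(NA_real_)
    j <- r[which.min(dist[r])]
    if (dist[j] > MATCH_WINDOW_DAYS) NA_real_ else ms$value[j]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Change in a measured parameter from baseline to a follow-up window
#'
#' For each patient, selects the measurement nearest the nominal window
#' timepoint (within ±6 weeks) and the measurement nearest enrollment
#' (same tolerance), and returns their difference. Either endpoint absent
#' yields `NA` — missingness is a value here, not an error.
#'
#' @param cohort a `patient_cohort`.
#' @param window_months follow-up window: 3, 6, 9 or 12.
#' @param parameter measured parameter name (default `"hba1c"`).
#' @return Data frame with `patient_id`, `baseline`, `endpoint`, `change`
#'   (endpoint minus baseline, in the parameter's units).
#' @export
#' @examples
#' # a patient going from HbA1c 8.2 to 7.4 has change -0.8
hba1c_change <- function(cohort, window_months = 6, parameter = "hba1c") {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (!window_months %in% c(3, 6, 9, 12)) {
    stop("window_months must be one of 3, 6, 9, 12", call. = FALSE)
  }
  baseline <- .value_at(cohort, parameter, 0)
  endpoint <- .value_at(cohort, parameter, window_months)
  data.frame(patient_id = cohort$patients$patient_id,
             baseline = baseline, endpoint = endpoint,
             change = endpoint - baseline,
             stringsAsFactors = FALSE)
}

#' Classify patients by treatment-target attainment
#'
#' Judged on the endpoint value alone against each patient's personal
#' target: `reached_or_maintained` when the endpoint satisfies the target
#' (at or below it for `at_most` parameters such as HbA1c; at or above it
#' for `at_least` parameters such as HDL cholesterol);
#' `improved_not_reached` when the endpoint misses the target but is
#' strictly better than baseline in the target direction; `not_improved`
#' otherwise; `missing` when either endpoint is absent. The four
#' categories partition the cohort.
#'
#' @param cohort a `patient_cohort`.
#' @param parameter measured parameter with a personal target.
#' @param window_months follow-up window (default 6).
#' @return Data frame with `patient_id`, `parameter`, `category` (factor
#'   with the four levels above).
#' @export
classify_target <- function(cohort, parameter = "hba1c",
                            window_months = 6) {
  stopifnot(inherits(cohort, "patient_cohort"))
  ms <- cohort$measurements
  if (!parameter %in% ms$parameter) {
    stop("unknown parameter '", parameter, "'; measured parameters: ",
         paste(unique(ms$parameter), collapse = ", "), call. = FALSE)
  }
  ch <- hba1c_change(cohort, window_months, parameter = parameter)
  msp <- ms[ms$parameter == parameter, , drop = FALSE]
  idx <- match(ch$patient_id, msp$patient_id)
  target <- msp$target_value[idx]
  direction <- msp$target_direction[idx]
  if (any(!direction[!is.na(direction)] %in% c("at_most", "at_least"))) {
    stop("target_direction must be 'at_most' or 'at_least'", call. = FALSE)
  }
  category <- vapply(seq_len(nrow(ch)), function(i) {
    b <- ch$baseline[i]; e <- ch$endpoint[i]
    t <- target[i]; d <- direction[i]
    if (is.na(b) || is.na(e) || is.na(t)) return("missing")
    reached <- if (d == "at_most") e <= t else e >= t
    if (reached) return("reached_or_maintained")
    improved <- if (d == "at_most") e < b else e > b
    if (improved) "improved_not_reached" else "not_improved"
  }, character(1))
  data.frame(patient_id = ch$patient_id, parameter = parameter,
             category = factor(category,
                               levels = c("reached_or_maintained",
                                          "improved_not_reached",
                                          "not_improved", "missing")),
             stringsAsFactors = FALSE)
}

#' Care-plan adherence, per item and overall
#'
#' Adherence is the percentage of planned tests or consultations actually
#' performed, prorated to each patient's follow-up duration: per item,
#' `min(1, performed / expected) * 100` with
#' `expected = planned_per_year * followup_months / 12`, floored at 1 (any
#' test planned at all is due at least once during a >= 6-month
#' follow-up). A patient's overall adherence is the unweighted mean of the
#' item percentages. Items with zero planned frequency are excluded with a
#' warning.
#'
#' @param cohort a `patient_cohort`.
#' @return A list with `per_item` (patient x item rows: `patient_id`,
#'   `item`, `planned_per_year`, `performed`, `expected`,
#'   `adherence_percent`) and `per_patient` (`patient_id`,
#'   `overall_percent`).
#' @export
#' @examples
#' # 4 planned/year over a 6-month follow-up -> 2 expected;
#' # 2 performed -> 100% for that item
adherence <- function(cohort) {
  stopifnot(inherits(cohort, "patient_cohort"))
  cp <- cohort$careplan
  if (nrow(cp) == 0L) {
    stop("cohort has no care-plan items", call. = FALSE)
  }
  zero <- cp$planned_per_year <= 0
  if (any(zero)) {
    warning(sum(zero), " care-plan item(s) with zero planned frequency ",
            "excluded from adherence", call. = FALSE)
    cp <- cp[!zero, , drop = FALSE]
  }
  fup <- cohort$patients$followup_months[
    match(cp$patient_id, cohort$patients$patient_id)]
  cp$expected <- pmax(1, cp$planned_per_year * fup / 12)
  cp$adherence_percent <- pmin(1, cp$performed / cp$expected) * 100
  per_patient <- aggregate(adherence_percent ~ patient_id, data = cp, mean)
  names(per_patient)[2L] <- "overall_percent"
  list(per_item = cp, per_patient = per_patient)
}

#' Cohort-level clinical summary
#'
#' Summarises a cohort the way an observational diabetes study reports its
#' clinical results: mean/SD/median/IQR of the parameter change over the
#' window (missing data excluded pairwise, with the missing count
#' reported), the share of paired patients with a clinically relevant
#' decrease (change at or below `relevant_change`), the distribution of
#' patients across HbA1c bands at baseline and at the window, the
#' target-attainment category counts, and the adherence distribution.
#'
#' @param cohort a `patient_cohort`.
#' @param parameter parameter to summarise (default `"hba1c"`).
#' @param window_months follow-up window (default 6).
#' @param band_breaks interior HbA1c band edges; the default
#'   `c(7, 8, 9)` yields bands `<7.0`, `7.0-7.9`, `8.0-8.9`, `>=9.0`.
#' @param relevant_change clinically relevant change threshold (default
#'   `-0.4` percentage points, a decrease of at least 0.4).
#' @return A list of class `cohort_summary` with components `n`,
#'   `n_type1`, `n_type2`, `change` (n_paired, n_missing, mean, sd,
#'   median, q1, q3, prop_relevant_decrease,
#'   prop_relevant_among_decreasers), `bands` (data frame of proportions
#'   at baseline and window), `targets` (category counts and
#'   proportions among paired), and `adherence` (mean_overall_percent,
#'   prop_above_70, per-item means).
#' @export
cohort_summary <- function(cohort, parameter = "hba1c", window_months = 6,
                           band_breaks = c(7, 8, 9),
                           relevant_change = -0.4) {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (nrow(cohort$patients) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  ch <- hba1c_change(cohort, window_months, parameter = parameter)
  paired <- ch[!is.na(ch$change), , drop = FALSE]
  qs <- if (nrow(paired) > 0L) {
    stats::quantile(paired$change, c(0.25, 0.5, 0.75), names = FALSE)
  } else rep(NA_real_, 3L)
  decreasers <- paired$change < 0

  breaks <- c(-Inf, band_breaks, Inf)
  labels <- c(paste0("<", format(band_breaks[1L], nsmall = 1)),
              paste0(format(band_breaks[-length(band_breaks)], nsmall = 1),
                     "-", format(band_breaks[-1L] - 0.1, nsmall = 1)),
              paste0(">=", format(band_breaks[length(band_breaks)],
                                  nsmall = 1)))
  band_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(rep(NA_real_, length(labels)))
    as.numeric(table(cut(x, breaks, labels = labels, right = FALSE))) /
      length(x)
  }
  bands <- data.frame(band = labels,
                      baseline_prop = band_of(ch$baseline),
                      window_prop = band_of(ch$endpoint),
                      stringsAsFactors = FALSE)

  cls <- classify_target(cohort, parameter, window_months)
  counts <- table(cls$category)
  n_paired_cls <- sum(counts[c("reached_or_maintained",
                               "improved_not_reached", "not_improved")])
  adh <- adherence(cohort)
  per_item_mean <- aggregate(adherence_percent ~ item,
                             data = adh$per_item, mean)

  structure(list(
    n = nrow(cohort$patients),
    n_type1 = sum(cohort$patients$diabetes_type == 1L),
    n_type2 = sum(cohort$patients$diabetes_type == 2L),
    change = list(
      n_paired = nrow(paired),
      n_missing = nrow(ch) - nrow(paired),
      mean = mean(paired$change),
      sd = stats::sd(paired$change),
      median = qs[2L], q1 = qs[1L], q3 = qs[3L],
      prop_relevant_decrease = mean(paired$change <= relevant_change),
      prop_relevant_among_decreasers =
        if (any(decreasers)) {
          mean(paired$change[decreasers] <= relevant_change)
        } else NA_real_
    ),
    bands = bands,
    targets = list(
      counts = counts,
      proportions = if (n_paired_cls > 0) {
        counts[c("reached_or_maintained", "improved_not_reached",
                 "not_improved")] / n_paired_cls
      } else counts[1:3] * NA_real_
    ),
    adherence = list(
      mean_overall_percent = mean(adh$per_patient$overall_percent),
      prop_above_70 = mean(adh$per_patient$overall_percent > 70),
      per_item_mean = per_item_mean
    )
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients (%d type 1 / %d type 2)\n",
              x$n, x$n_type1, x$n_type2))
  cat(sprintf("Paired change: n=%d (missing %d), mean %.2f (SD %.2f), ",
              x$change$n_paired, x$change$n_missing, x$change$mean,
              x$change$sd))
  cat(sprintf("median %.2f (IQR %.2f to %.2f)\n", x$change$median,
              x$change$q1, x$change$q3))
  cat(sprintf("Target attainment: %s\n",
              paste(names(x$targets$counts), as.integer(x$targets$counts),
                    sep = "=", collapse = ", ")))
  cat(sprintf("Mean overall adherence: %.1f%% (%.0f%% of patients >70%%)\n",
              x$adherence$mean_overall_percent,
              100 * x$adherence$prop_above_70))
  invisible(x)
}
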