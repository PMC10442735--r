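# ---------------------------------------------------------------------------
# Synthetic patient cohort generator.
#
# Emulates the structure of the observational nurse-educator study: 117
# patients (8 type 1 / 109 type 2), baseline HbA1c mean 7.8 (SD 1.4),
# 6-month change mean -0.6 (SD 1.3), 79/117 with paired baseline/6-month
# values, per-patient care plans with partial completion.
#
# Physiological truncation is applied through symmetric acceptance
# regions (the configured range intersected with its reflection about the
# target mean), so truncation never shifts the generated means away from
# the study values the generator is calibrated to.
# ---------------------------------------------------------------------------

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the observational study's structure: n = 117
#' patients with a type-1 fraction of 8/117, baseline HbA1c mean 7.8 (SD
#' 1.4) percent, 6-month change mean -0.6 (SD 1.3) percentage points,
#' paired-data availability 79/117, a personal HbA1c target of 7.0%
#' (direction `at_most`), and the study's care-plan items (quarterly
#' HbA1c tests and nurse/doctor consultations, twice-yearly lipid and
#' urine albumin tests, annual dietetic consultation and eye and foot
#' examinations) with completion probabilities matching the reported
#' per-item adherence pattern (near-complete for tests and consultations,
#' partial for dietetic consultations and examinations).
#'
#' @param n number of patients.
#' @param type1_fraction fraction with type 1 diabetes.
#' @param baseline_mean,baseline_sd baseline HbA1c distribution (percent).
#' @param change_mean,change_sd 6-month HbA1c change distribution
#'   (percentage points).
#' @param paired_fraction fraction of patients with both baseline and
#'   6-month values.
#' @param baseline_range plausible baseline HbA1c range (percent).
#' @param min_value floor for any generated HbA1c value (percent).
#' @param target_value,target_direction personal HbA1c target.
#' @param followup_choices,followup_probs follow-up duration distribution
#'   (months; all choices must be >= 6).
#' @param careplan data frame `item`, `planned_per_year`,
#'   `completion_prob`.
#' @param stratified if `TRUE`, subgroup counts are exact
#'   (`round(n * fraction)` type-1 and paired patients) rather than
#'   binomial, so tests can pin exact denominators.
#' @param start_date first possible enrollment date.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 117L,
                        type1_fraction = 8 / 117,
                        baseline_mean = 7.8, baseline_sd = 1.4,
                        change_mean = -0.6, change_sd = 1.3,
                        paired_fraction = 79 / 117,
                        baseline_range = c(4.5, 15),
                        min_value = 4,
                        target_value = 7.0,
                        target_direction = "at_most",
                        followup_choices = c(6, 12),
                        followup_probs = c(0.5, 0.5),
                        careplan = data.frame(
                          item = c("hba1c_test", "lipid_test", "mau_test",
                                   "dne_consult", "doctor_consult",
                                   "dietetic_consult", "eye_exam",
                                   "foot_exam"),
                          planned_per_year = c(4, 2, 2, 4, 4, 1, 1, 1),
                          completion_prob = c(0.99, 0.98, 0.98, 0.99, 0.98,
                                              0.59, 0.57, 0.44),
                          stringsAsFactors = FALSE),
                        stratified = FALSE,
                        start_date = as.Date("2019-11-25")) {
  spec <- list(n = as.integer(n), type1_fraction = type1_fraction,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               change_mean = change_mean, change_sd = change_sd,
               paired_fraction = paired_fraction,
               baseline_range = baseline_range, min_value = min_value,
               target_value = target_value,
               target_direction = target_direction,
               followup_choices = followup_choices,
               followup_probs = followup_probs,
               careplan = careplan, stratified = isTRUE(stratified),
               start_date = as.Date(start_date))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#' @param spec a `cohort_spec`.
#' @return The spec, invisibly; errors name the offending field.
#' @export
validate_cohort_spec <- function(spec) {
  if (spec$n <= 0L) stop("validation error: n must be > 0", call. = FALSE)
  for (f in c("type1_fraction", "paired_fraction")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) {
      stop("validation error: ", f, " must lie in [0, 1], got ", spec[[f]],
           call. = FALSE)
    }
  }
  if (spec$baseline_sd < 0 || spec$change_sd < 0) {
    stop("validation error: standard deviations must be >= 0",
         call. = FALSE)
  }
  if (diff(spec$baseline_range) <= 0) {
    stop("validation error: baseline_range must be increasing",
         call. = FALSE)
  }
  if (any(spec$followup_choices < 6)) {
    stop("validation error: follow-up must be at least 6 months",
         call. = FALSE)
  }
  .require_fields(spec$careplan,
                  c("item", "planned_per_year", "completion_prob"),
                  "careplan")
  if (any(spec$careplan$completion_prob < 0 |
          spec$careplan$completion_prob > 1)) {
    stop("validation error: completion_prob must lie in [0, 1]",
         call. = FALSE)
  }
  invisible(spec)
}

# draw from N(mean, sd) restricted to the symmetric part of [lo, hi]
# around `mean`; symmetry keeps the truncated mean equal to `mean`.
# Degenerate regions (mean outside [lo, hi]) collapse to the nearest
# bound.
.rnorm_sym_trunc <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  if (sd == 0) return(pmin(hi, pmax(lo, mean)))
  lo2 <- rep_len(pmax(lo, 2 * mean - hi), n)
  hi2 <- rep_len(pmin(hi, 2 * mean - lo), n)
  out <- numeric(n)
  # near-zero-width intervals (incl. floating-point residue) collapse to
  # the clamped mean instead of entering rejection sampling
  degenerate <- hi2 - lo2 <= 1e-8
  out[degenerate] <- pmin(hi, pmax(lo, mean))[degenerate]
  todo <- which(!degenerate)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean[todo], sd)
    ok <- draw >= lo2[todo] & draw <= hi2[todo]
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Deterministic given `seed`. Baseline HbA1c is drawn from a truncated
#' normal on the spec's plausible range; the 6-month value is baseline
#' plus a normal change, floored at the spec's minimum; both truncations
#' use symmetric acceptance regions so the generated means stay at the
#' spec's targets. Intermediate (3-month) and later (9/12-month)
#' measurements interpolate and then hold the 6-month level with small
#' residual noise, reflecting the model assumption that HbA1c is stable
#' beyond 6 months. All HbA1c values are reported to 0.1%, as a
#' laboratory would. Care-plan events are binomial on the prorated
#' planned counts with the per-item completion probabilities. Patients
#' without paired data lack the 6-month measurement.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed; same seed, same cohort.
#' @return A `patient_cohort`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(stratified = TRUE), seed = 1)
#' sum(coh$patients$diabetes_type == 1)  # exactly 8
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  validate_cohort_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  ids <- sprintf("P%04d", seq_len(n))

  if (spec$stratified) {
    n1 <- round(n * spec$type1_fraction)
    type1 <- seq_len(n) %in% sample.int(n, n1)
    np <- round(n * spec$paired_fraction)
    paired <- seq_len(n) %in% sample.int(n, np)
  } else {
    type1 <- stats::runif(n) < spec$type1_fraction
    paired <- stats::runif(n) < spec$paired_fraction
  }

  enrollment <- spec$start_date + sample.int(200, n, replace = TRUE) - 1L
  followup <- sample(spec$followup_choices, n, replace = TRUE,
                     prob = spec$followup_probs)

  baseline <- round(.rnorm_sym_trunc(n, spec$baseline_mean,
                                     spec$baseline_sd,
                                     spec$baseline_range[1L],
                                     spec$baseline_range[2L]) / 0.1) * 0.1
  value6 <- round(.rnorm_sym_trunc(n, baseline + spec$change_mean,
                                   spec$change_sd,
                                   spec$min_value, Inf) / 0.1) * 0.1

  days_per_month <- 30.4375
  schedule <- c(0, 3, 6, 9, 12)
  idx <- rep(seq_len(n), each = length(schedule))
  month <- rep(schedule, times = n)
  keep <- month <= followup[idx] & !(month == 6 & !paired[idx])
  idx <- idx[keep]
  month <- month[keep]
  anchor <- ifelse(month < 6, (baseline[idx] + value6[idx]) / 2,
                   value6[idx])
  noisy <- round(pmax(spec$min_value,
                      anchor + stats::rnorm(length(idx), 0, 0.3)) /
                   0.1) * 0.1
  value <- ifelse(month == 0, baseline[idx],
                  ifelse(month == 6, value6[idx], noisy))
  measurements <- data.frame(
    patient_id = ids[idx],
    parameter = "hba1c",
    date = enrollment[idx] + round(month * days_per_month) +
      sample(-10:10, length(idx), replace = TRUE),
    value = value,
    target_value = spec$target_value,
    target_direction = spec$target_direction,
    stringsAsFactors = FALSE
  )

  cp <- spec$careplan
  idx2 <- rep(seq_len(n), each = nrow(cp))
  planned <- rep(cp$planned_per_year, times = n)
  expected <- pmax(1, planned * followup[idx2] / 12)
  careplan <- data.frame(
    patient_id = ids[idx2],
    item = rep(cp$item, times = n),
    planned_per_year = planned,
    performed = stats::rbinom(length(idx2), ceiling(expected - 1e-9),
                              rep(cp$completion_prob, times = n)),
    stringsAsFactors = FALSE
  )

  patients <- data.frame(
    patient_id = ids,
    diabetes_type = ifelse(type1, 1L, 2L),
    enrollment_date = enrollment,
    followup_months = followup,
    stringsAsFactors = FALSE
  )
  patient_cohort(patients, measurements, careplan)
}

#' Write a cohort to CSV files
#'
#' Emits the two files consumed by the clinical pipeline: a measurement
#' table (one row per patient-measurement, carrying the patient-level
#' fields) and a companion care-plan table. Reading them back with
#' [read_cohort()] round-trips value-identically.
#'
#' @param cohort a `patient_cohort`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"cohort"`).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meas_path <- file.path(dir, paste0(prefix, "_measurements.csv"))
  plan_path <- file.path(dir, paste0(prefix, "_careplan.csv"))
  meas <- merge(cohort$patients, cohort$measurements, by = "patient_id",
                sort = FALSE)
  meas <- meas[order(meas$patient_id, meas$date), , drop = FALSE]
  utils::write.csv(meas, meas_path, row.names = FALSE)
  utils::write.csv(cohort$careplan, plan_path, row.names = FALSE)
  invisible(c(measurements = meas_path, careplan = plan_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param measurements_path path to the measurement CSV.
#' @param careplan_path path to the care-plan CSV.
#' @return A `patient_cohort`.
#' @export
read_cohort <- function(measurements_path, careplan_path) {
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  plan <- utils::read.csv(careplan_path, stringsAsFactors = FALSE)
  pat_cols <- c("patient_id", "diabetes_type", "enrollment_date",
                "followup_months")
  .require_fields(meas, c(pat_cols, "parameter", "date", "value",
                          "target_value", "target_direction"),
                  "measurements file")
  patients <- unique(meas[, pat_cols, drop = FALSE])
  rownames(patients) <- NULL
  patients$diabetes_type <- as.integer(patients$diabetes_type)
  patients$followup_months <- as.numeric(patients$followup_months)
  measurements <- meas[, c("patient_id", "parameter", "date", "value",
                           "target_value", "target_direction"),
                       drop = FALSE]
  rownames(measurements) <- NULL
  measurements$value <- as.numeric(measurements$value)
  measurements$target_value <- as.numeric(measurements$target_value)
  plan$planned_per_year <- as.numeric(plan$planned_per_year)
  plan$performed <- as.integer(plan$performed)
  patient_cohort(patients, measurements, plan)
}
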