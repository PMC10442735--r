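# Independent oracles, deliberately written without reference to the
# package internals.

# Risk multiplier by explicit 0.1%-step summation: each full 0.1% of
# excess HbA1c above the threshold adds increment/10 to the multiplier.
step_multiplier_oracle <- function(hba1c, threshold, increment) {
  excess <- max(0, hba1c - threshold)
  n_steps <- floor(excess * 10 + 0.5 + 1e-9)
  mult <- 1
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) mult <- mult + increment / 10
  }
  mult
}

# Brute-force scenario complication cost for one model year: scalar loop
# over complications using the closed-form multiplier directly.
brute_complication_cost <- function(config, cohort_label, year) {
  co <- config$cohorts[config$cohorts$label == cohort_label, ]
  pop <- config$population$prevalence[year] +
    config$population$incidence[year]
  total <- 0
  for (m in seq_len(nrow(config$complications))) {
    comp <- config$complications[m, ]
    rule <- config$risk_rules[
      config$risk_rules$complication_class == comp$complication_class, ]
    mult_of <- function(h) {
      1 + rule$increment_per_point_fraction *
        floor(max(0, h - rule$threshold_percent) * 10 + 0.5 + 1e-9) / 10
    }
    inc6 <- min(1, comp$baseline_incidence_fraction *
                  mult_of(co$hba1c_6mo_percent))
    inc <- if (year == 1) {
      inc0 <- min(1, comp$baseline_incidence_fraction *
                    mult_of(co$hba1c_baseline_percent))
      (inc0 + inc6) / 2
    } else {
      inc6
    }
    total <- total + inc * pop * comp$cost_2021_zar
  }
  total
}

# Tiny hand-built cohort for clinical pipeline tests: one row per
# patient with chosen baseline/6-month HbA1c values.
make_tiny_cohort <- function(baseline, month6, target = 7.0,
                             direction = "at_most", parameter = "hba1c",
                             followup = 6,
                             careplan = NULL) {
  n <- length(baseline)
  ids <- sprintf("T%02d", seq_len(n))
  enr <- as.Date("2020-01-01")
  patients <- data.frame(patient_id = ids, diabetes_type = 2L,
                         enrollment_date = enr,
                         followup_months = followup)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = ids[i], parameter = parameter, date = enr,
      value = baseline[i], target_value = target,
      target_direction = direction)
    if (!is.na(month6[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = ids[i], parameter = parameter,
        date = enr + round(6 * 30.4375),
        value = month6[i], target_value = target,
        target_direction = direction)
    }
  }
  if (is.null(careplan)) {
    careplan <- data.frame(patient_id = ids, item = "hba1c_test",
                           planned_per_year = 4, performed = 2L)
  }
  patient_cohort(patients, do.call(rbind, rows), careplan)
}
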