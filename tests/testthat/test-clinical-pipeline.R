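test_that("HbA1c change picks nearest measurements around the window", {
  coh <- make_tiny_cohort(baseline = c(8.2, 7.5, 8.0),
                          month6 = c(7.4, 7.5, NA))
  ch <- hba1c_change(coh, 6)
  expect_equal(ch$change, c(-0.8, 0.0, NA))
  expect_error(hba1c_change(coh, 5), "window_months")
})

test_that("measurements outside the ±6-week window are not matched", {
  enr <- as.Date("2020-01-01")
  patients <- data.frame(patient_id = "A", diabetes_type = 2L,
                         enrollment_date = enr, followup_months = 12)
  # one baseline, one value 9 weeks past the 6-month point, and a 9-month
  # value: the 6-month window must stay empty, the 9-month one filled
  meas <- data.frame(patient_id = "A", parameter = "hba1c",
                     date = enr + c(0, 183 + 63, 274),
                     value = c(8.0, 7.0, 6.8),
                     target_value = 7, target_direction = "at_most")
  plan <- data.frame(patient_id = "A", item = "hba1c_test",
                     planned_per_year = 4, performed = 4L)
  coh <- patient_cohort(patients, meas, plan)
  expect_true(is.na(hba1c_change(coh, 6)$change))
  expect_equal(hba1c_change(coh, 9)$change, -1.2)
  # with two candidates near the window, the nearer one wins
  meas2 <- rbind(meas,
                 data.frame(patient_id = "A", parameter = "hba1c",
                            date = enr + 190, value = 7.5,
                            target_value = 7,
                            target_direction = "at_most"))
  coh2 <- patient_cohort(patients, meas2, plan)
  expect_equal(hba1c_change(coh2, 6)$change, -0.5)
})

test_that("target attainment categories follow endpoint and direction", {
  coh <- make_tiny_cohort(baseline = c(8.0, 8.0, 8.0, 8.0),
                          month6 = c(6.9, 7.5, 8.3, NA), target = 7.0)
  cls <- classify_target(coh)
  expect_equal(as.character(cls$category),
               c("reached_or_maintained", "improved_not_reached",
                 "not_improved", "missing"))
  # an at_least parameter (HDL) flips the direction of improvement
  hdl <- make_tiny_cohort(baseline = c(0.9, 0.9), month6 = c(0.8, 1.1),
                          target = 1.0, direction = "at_least",
                          parameter = "hdl")
  cls_hdl <- classify_target(hdl, parameter = "hdl")
  expect_equal(as.character(cls_hdl$category),
               c("not_improved", "reached_or_maintained"))
  expect_error(classify_target(coh, parameter = "ldl"),
               "unknown parameter")
})

test_that("categories partition the cohort exactly", {
  coh <- generate_cohort(cohort_spec(stratified = TRUE), seed = 42)
  cls <- classify_target(coh)
  expect_equal(sum(table(cls$category)), nrow(coh$patients))
  ch <- hba1c_change(coh, 6)
  paired <- sum(!is.na(ch$change))
  counts <- table(cls$category)
  expect_equal(sum(counts[c("reached_or_maintained",
                            "improved_not_reached", "not_improved")]),
               paired)
  expect_equal(unname(counts["missing"]), nrow(coh$patients) - paired)
})

test_that("adherence prorates planned counts to follow-up duration", {
  ids <- c("A", "B", "C")
  patients <- data.frame(patient_id = ids, diabetes_type = 2L,
                         enrollment_date = as.Date("2020-01-01"),
                         followup_months = c(6, 12, 6))
  meas <- data.frame(patient_id = ids, parameter = "hba1c",
                     date = as.Date("2020-01-01"), value = 8,
                     target_value = 7, target_direction = "at_most")
  plan <- data.frame(
    patient_id = c("A", "B", "C", "C"),
    item = c("hba1c_test", "lipid_test", "eye_exam", "foot_exam"),
    planned_per_year = c(4, 2, 1, 1),
    performed = c(2L, 1L, 1L, 0L))
  coh <- patient_cohort(patients, meas, plan)
  adh <- adherence(coh)
  # 4/yr over 6 months -> 2 expected, 2 performed -> 100%
  expect_equal(adh$per_item$adherence_percent[1], 100)
  # 2/yr over 12 months -> 2 expected, 1 performed -> 50%
  expect_equal(adh$per_item$adherence_percent[2], 50)
  # 1/yr over 6 months: expected floored at 1, so 1 performed -> 100%
  expect_equal(adh$per_item$expected[3], 1)
  expect_equal(adh$per_item$adherence_percent[3], 100)
  # overall is the unweighted mean of the patient's items
  expect_equal(adh$per_patient$overall_percent,
               c(100, 50, mean(c(100, 0))))
  expect_true(all(adh$per_item$adherence_percent >= 0 &
                    adh$per_item$adherence_percent <= 100))
})

test_that("zero planned frequency is excluded with a warning", {
  coh <- make_tiny_cohort(baseline = 8, month6 = 7.5,
                          careplan = data.frame(
                            patient_id = "T01",
                            item = c("hba1c_test", "retired_item"),
                            planned_per_year = c(4, 0),
                            performed = c(2L, 0L)))
  expect_warning(adh <- adherence(coh), "zero planned")
  expect_equal(nrow(adh$per_item), 1L)
})

test_that("zero performed events give zero overall adherence", {
  coh <- make_tiny_cohort(baseline = 8, month6 = 7.5,
                          careplan = data.frame(
                            patient_id = "T01",
                            item = c("hba1c_test", "eye_exam"),
                            planned_per_year = c(4, 1),
                            performed = c(0L, 0L)))
  adh <- adherence(coh)
  expect_equal(adh$per_patient$overall_percent, 0)
})

test_that("cohort summary reproduces straightforward statistics", {
  coh <- make_tiny_cohort(baseline = c(8.0, 7.5), month6 = c(7.0, 7.5))
  s <- cohort_summary(coh)
  expect_equal(s$change$mean, -0.5)
  expect_equal(s$change$sd, sd(c(-1, 0)))
  expect_equal(s$change$n_paired, 2)
  # every endpoint below 7 -> all mass in the lowest band
  low <- make_tiny_cohort(baseline = c(8.0, 9.5), month6 = c(6.5, 6.9))
  sl <- cohort_summary(low)
  expect_equal(sl$bands$window_prop[sl$bands$band == "<7.0"], 1)
  expect_error(cohort_summary(patient_cohort(
    data.frame(patient_id = character(), diabetes_type = integer(),
               enrollment_date = as.Date(character()),
               followup_months = numeric()),
    data.frame(patient_id = character(), parameter = character(),
               date = as.Date(character()), value = numeric(),
               target_value = numeric(), target_direction = character()),
    data.frame(patient_id = character(), item = character(),
               planned_per_year = numeric(), performed = integer()))),
    "empty cohort")
})

test_that("summary statistics match an independent recomputation", {
  coh <- generate_cohort(cohort_spec(stratified = TRUE), seed = 7)
  s <- cohort_summary(coh)
  ch <- hba1c_change(coh, 6)$change
  ch <- ch[!is.na(ch)]
  expect_equal(s$change$mean, mean(ch))
  expect_equal(s$change$sd, sd(ch))
  expect_equal(s$change$median, median(ch))
  expect_equal(s$change$q1, unname(quantile(ch, 0.25)))
  expect_equal(s$change$prop_relevant_decrease, mean(ch <= -0.4))
  # band proportions sum to one at both timepoints
  expect_equal(sum(s$bands$baseline_prop), 1)
  expect_equal(sum(s$bands$window_prop), 1)
})
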