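cfg <- default_config()
macro <- get_risk_rule(cfg, "macrovascular")
micro <- get_risk_rule(cfg, "microvascular")
comps <- cfg$complications
rownames(comps) <- comps$name

test_that("risk multiplier matches the 0.1%-step oracle at key levels", {
  # at or below threshold risk is flat
  expect_identical(risk_multiplier(7.0, macro), 1)
  expect_identical(risk_multiplier(6.0, micro), 1)
  # twelve 0.1-steps of 3.8% above the 7.0 macrovascular threshold
  expect_equal(step_multiplier_oracle(8.2, 7.0, 0.38), 1.456)
  expect_equal(risk_multiplier(8.2, macro), 1.456)
  # twenty-five 0.1-steps of 4.0% above the 6.5 microvascular threshold
  expect_equal(step_multiplier_oracle(9.0, 6.5, 0.40), 2.00)
  expect_equal(risk_multiplier(9.0, micro), 2.00)
})

test_that("closed form and step oracle agree on the full 0.1 grid", {
  grid <- seq(4, 20, by = 0.1)
  for (rule in list(macro, micro)) {
    oracle <- vapply(grid, step_multiplier_oracle,
                     numeric(1),
                     threshold = rule$threshold_percent,
                     increment = rule$increment_per_point_fraction)
    expect_equal(risk_multiplier(grid, rule), oracle, tolerance = 1e-12)
  }
})

test_that("risk multiplier is non-decreasing and 1 below threshold", {
  grid <- seq(4, 20, by = 0.05)
  for (rule in list(macro, micro)) {
    mults <- risk_multiplier(grid, rule)
    expect_true(all(diff(mults) >= 0))
    expect_true(all(mults[grid <= rule$threshold_percent] == 1))
    expect_true(all(mults >= 1))
  }
})

test_that("adjusted incidence scales baseline by the class multiplier", {
  expect_equal(adjusted_incidence(comps["nephropathy", ], 9.0,
                                  cfg$risk_rules), 0.50)
  expect_equal(adjusted_incidence(comps["myocardial_infarction", ], 7.0,
                                  cfg$risk_rules), 0.06)
  expect_equal(adjusted_incidence(comps["retinopathy", ], 7.2,
                                  cfg$risk_rules), 0.15 * 1.28)
  # equals baseline at or below the threshold
  expect_equal(adjusted_incidence(comps["nephropathy", ], 6.5,
                                  cfg$risk_rules), 0.25)
  # capped at 1 for extreme parameter combinations
  big <- comps["nephropathy", ]
  big$baseline_incidence_fraction <- 0.9
  expect_equal(adjusted_incidence(big, 15, cfg$risk_rules), 1)
  # never exceeds 1 anywhere on the plausible grid
  expect_true(all(adjusted_incidence(big, seq(4, 20, 0.1),
                                     cfg$risk_rules) <= 1))
  bad <- comps["stroke", ]
  bad$complication_class <- "mediovascular"
  expect_error(adjusted_incidence(bad, 8, cfg$risk_rules),
               "unknown complication class")
})

test_that("year-1 averages the two half-years; later years hold at 6 months", {
  soc <- cfg$cohorts[cfg$cohorts$label == "standard_of_care", ]
  neph <- comps["nephropathy", ]
  expect_equal(year_incidence(neph, soc, 1, cfg$risk_rules),
               mean(c(0.50, 0.42)))
  expect_equal(year_incidence(neph, soc, 3, cfg$risk_rules), 0.25 * 1.68)
  for (k in 2:5) {
    expect_equal(year_incidence(neph, soc, k, cfg$risk_rules),
                 year_incidence(neph, soc, 2, cfg$risk_rules))
  }
  flat <- soc
  flat$hba1c_6mo_percent <- flat$hba1c_baseline_percent
  expect_equal(year_incidence(neph, flat, 1, cfg$risk_rules),
               adjusted_incidence(neph, flat$hba1c_baseline_percent,
                                  cfg$risk_rules))
  expect_error(year_incidence(neph, soc, 6, cfg$risk_rules), "1..5")
})

test_that("adjusted incidence table covers complication x cohort x year", {
  tab <- adjusted_incidence_table(cfg)
  expect_equal(nrow(tab), 7 * 2 * 5)
  expect_true(all(tab$incidence_fraction > 0 & tab$incidence_fraction <= 1))
  # above-threshold cohorts never fall below baseline incidence
  base <- comps[tab$complication, "baseline_incidence_fraction"]
  expect_true(all(tab$incidence_fraction >= base))
})
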