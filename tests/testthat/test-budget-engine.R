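cfg <- default_config()
model <- run_budget_model(cfg)

test_that("totals conserve: complication + monitoring = total, every year", {
  for (res in list(model$without, model$with)) {
    expect_identical(res$years$total_cost_zar,
                     res$years$complication_cost_zar +
                       res$years$monitoring_cost_zar)
    expect_true(all(unlist(res$years) >= 0))
    expect_equal(unname(colSums(res$costs)),
                 res$years$complication_cost_zar)
  }
})

test_that("engine agrees with the brute-force per-complication oracle", {
  for (label in cfg$cohorts$label) {
    res <- scenario_costs(cfg, label)
    for (k in 1:5) {
      expect_equal(res$years$complication_cost_zar[k],
                   brute_complication_cost(cfg, label, k),
                   tolerance = 1e-6)
    }
  }
})

test_that("budget impact is the element-wise scenario difference", {
  bi <- model$impact
  expect_equal(bi$years$net_impact_zar,
               model$without$years$total_cost_zar -
                 model$with$years$total_cost_zar)
  expect_equal(bi$cumulative_net_impact_zar, sum(bi$years$net_impact_zar))
  expect_equal(bi$per_patient_year1_zar,
               bi$years$net_impact_zar[1] / bi$years$treated_population[1])
  expect_equal(per_patient_net_impact(bi), bi$per_patient_year1_zar)
})

test_that("budget impact is antisymmetric in its two scenarios", {
  fwd <- budget_impact(model$without, model$with)
  rev <- budget_impact(model$with, model$without)
  expect_equal(fwd$years$net_impact_zar, -rev$years$net_impact_zar)
  expect_equal(fwd$events_avoided, -rev$events_avoided)
  expect_equal(fwd$costs_avoided, -rev$costs_avoided)
  expect_equal(fwd$cumulative_net_impact_zar,
               -rev$cumulative_net_impact_zar)
})

test_that("identical cohorts and monitoring give exactly zero impact", {
  same <- cfg
  same$cohorts$hba1c_baseline_percent <-
    rep(cfg$cohorts$hba1c_baseline_percent[1], 2)
  same$cohorts$hba1c_6mo_percent <- rep(cfg$cohorts$hba1c_6mo_percent[1], 2)
  same$monitoring$annual_cost_per_patient_zar <-
    rep(cfg$monitoring$annual_cost_per_patient_zar[1], 2)
  bi <- run_budget_model(same)$impact
  expect_identical(unique(bi$years$net_impact_zar), 0)
  expect_identical(max(abs(bi$events_avoided)), 0)
  expect_identical(bi$per_patient_year1_zar, 0)
})

test_that("zero baseline incidences give zero complication cost", {
  zero <- cfg
  zero$complications$baseline_incidence_fraction <- 0
  res <- scenario_costs(zero, "standard_of_care")
  expect_identical(unique(res$years$complication_cost_zar), 0)
  expect_true(all(res$years$monitoring_cost_zar > 0))
})

test_that("cost outputs are linear in the unit costs", {
  scaled <- cfg
  scaled$complications$cost_2021_zar <- cfg$complications$cost_2021_zar * 3
  scaled$monitoring$annual_cost_per_patient_zar <-
    cfg$monitoring$annual_cost_per_patient_zar * 3
  bi0 <- model$impact
  bi3 <- run_budget_model(scaled)$impact
  expect_equal(bi3$years$net_impact_zar, 3 * bi0$years$net_impact_zar)
  expect_equal(bi3$costs_avoided, 3 * bi0$costs_avoided)
  # events are cost-independent
  expect_equal(bi3$events_avoided, bi0$events_avoided)
})

test_that("raising the intervention 6-month HbA1c never increases savings", {
  levels <- seq(6.5, 9.0, by = 0.25)
  nets <- vapply(levels, function(h) {
    c2 <- cfg
    c2$cohorts$hba1c_6mo_percent[c2$cohorts$label == "mydiacare"] <- h
    run_budget_model(c2)$impact$years$net_impact_zar[1]
  }, numeric(1))
  expect_true(all(diff(nets) <= 1e-9))
})

test_that("market-share scaling multiplies deltas year by year", {
  bi <- model$impact
  expect_equal(market_share_scenario(bi, rep(1, 5)), bi)
  zero <- market_share_scenario(bi, rep(0, 5))
  expect_identical(unique(zero$years$net_impact_zar), 0)
  sh <- c(0.02, 0.03, 0.04, 0.05, 0.06)
  ms <- market_share_scenario(bi, sh)
  expect_equal(ms$years$net_impact_zar, bi$years$net_impact_zar * sh)
  expect_equal(ms$cumulative_net_impact_zar,
               sum(bi$years$net_impact_zar * sh))
  expect_error(market_share_scenario(bi, c(0.5, 0.5)), "per model year")
  expect_error(market_share_scenario(bi, rep(1.2, 5)), "\\[0, 1\\]")
})

test_that("mismatched scenarios are rejected", {
  other <- cfg
  other$population$prevalence <- cfg$population$prevalence * 2
  a <- scenario_costs(cfg, "standard_of_care")
  b <- scenario_costs(other, "mydiacare")
  expect_error(budget_impact(a, b), "population")
  expect_error(scenario_costs(cfg, "nonexistent"), "unknown cohort")
})
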