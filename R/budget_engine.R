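# ---------------------------------------------------------------------------
# Scenario cost projection and budget impact.
#
# treated_population(k) = prevalence(k) + incident cases(k): the model
# treats patients diagnosed during a year as managed (and monitored) in
# that year. Year-1 this is 328,118 + 43,410 = 371,528 patients.
# ---------------------------------------------------------------------------

#' Treated population per model year
#' @param population the `population` block of a config.
#' @return Numeric vector of length 5.
#' @export
treated_population <- function(population) {
  population$prevalence + population$incidence
}

#' Project scenario costs over the model horizon
#'
#' For one scenario cohort, computes per model year: expected complication
#' events (`year_incidence x treated population`, by complication),
#' complication cost (`events x 2021 unit cost`), monitoring cost
#' (per-patient annual monitoring cost `x` treated population), and their
#' total.
#'
#' @param config a `diabudget_config`.
#' @param cohort_label label of the cohort in `config$cohorts` (also used
#'   to select the monitoring profile in `config$monitoring`).
#' @return An object of class `scenario_result`: a list with `cohort`,
#'   `years` (data frame: `year`, `treated_population`,
#'   `complication_cost_zar`, `monitoring_cost_zar`, `total_cost_zar`),
#'   `events` (complication x year matrix of expected event counts) and
#'   `costs` (complication x year matrix of ZAR).
#' @export
#' @examples
#' res <- scenario_costs(default_config(), "standard_of_care")
#' res$years$complication_cost_zar[1] / 1e9  # ~115 billion ZAR
scenario_costs <- function(config, cohort_label) {
  validate_model_config(config)
  co <- config$cohorts
  i <- which(co$label == cohort_label)
  if (length(i) != 1L) {
    stop("unknown cohort label '", cohort_label, "'; available: ",
         paste(co$label, collapse = ", "), call. = FALSE)
  }
  cohort <- co[i, , drop = FALSE]
  mo <- config$monitoring
  j <- which(mo$scenario == cohort_label)
  if (length(j) != 1L) {
    stop("no monitoring profile for scenario '", cohort_label, "'",
         call. = FALSE)
  }
  monitoring_pp <- mo$annual_cost_per_patient_zar[j]

  horizon <- config$settings$horizon_years
  if (nrow(config$population) != horizon) {
    stop("population projection covers ", nrow(config$population),
         " years but the horizon is ", horizon, call. = FALSE)
  }
  pop <- treated_population(config$population)
  cp <- config$complications

  inc <- sapply(seq_len(horizon), function(k) {
    vapply(seq_len(nrow(cp)), function(m) {
      year_incidence(cp[m, , drop = FALSE], cohort, k, config$risk_rules)
    }, numeric(1))
  })
  events <- inc * rep(pop, each = nrow(cp))
  costs <- events * cp$cost_2021_zar
  dimnames(events) <- dimnames(costs) <- list(cp$name,
                                              paste0("year", 1:horizon))

  years <- data.frame(
    year = seq_len(horizon),
    treated_population = pop,
    complication_cost_zar = colSums(costs),
    monitoring_cost_zar = monitoring_pp * pop
  )
  years$total_cost_zar <- years$complication_cost_zar +
    years$monitoring_cost_zar
  rownames(years) <- NULL

  structure(list(cohort = cohort_label, years = years, events = events,
                 costs = costs),
            class = "scenario_result")
}

#' Budget impact of one scenario over another
#'
#' Element-wise differences, scenario-without minus scenario-with: events
#' avoided and cost avoided by complication and year, net budget impact
#' per year (total cost without minus total cost with), the cumulative
#' net impact over the horizon, and the year-1 net impact per treated
#' patient. A positive net impact is money saved by the "with" scenario.
#'
#' @param without `scenario_result` for the comparator (standard of care).
#' @param with_ `scenario_result` for the intervention scenario.
#' @return An object of class `budget_impact_result`: a list with `years`
#'   (data frame: `year`, `treated_population`,
#'   `complication_cost_avoided_zar`, `monitoring_cost_delta_zar`,
#'   `net_impact_zar`), `events_avoided` and `costs_avoided`
#'   (complication x year matrices), `cumulative_net_impact_zar`, and
#'   `per_patient_year1_zar`.
#' @export
budget_impact <- function(without, with_) {
  stopifnot(inherits(without, "scenario_result"),
            inherits(with_, "scenario_result"))
  if (nrow(without$years) != nrow(with_$years)) {
    stop("scenario horizons differ (", nrow(without$years), " vs ",
         nrow(with_$years), " years)", call. = FALSE)
  }
  if (!isTRUE(all.equal(without$years$treated_population,
                        with_$years$treated_population))) {
    stop("scenarios were run on different population projections",
         call. = FALSE)
  }
  events_avoided <- without$events - with_$events
  costs_avoided <- without$costs - with_$costs
  years <- data.frame(
    year = without$years$year,
    treated_population = without$years$treated_population,
    complication_cost_avoided_zar = without$years$complication_cost_zar -
      with_$years$complication_cost_zar,
    monitoring_cost_delta_zar = with_$years$monitoring_cost_zar -
      without$years$monitoring_cost_zar,
    net_impact_zar = without$years$total_cost_zar - with_$years$total_cost_zar
  )
  structure(list(
    years = years,
    events_avoided = events_avoided,
    costs_avoided = costs_avoided,
    cumulative_net_impact_zar = sum(years$net_impact_zar),
    per_patient_year1_zar = years$net_impact_zar[1L] /
      years$treated_population[1L]
  ), class = "budget_impact_result")
}

#' Year-1 net budget impact per treated patient
#'
#' @param result a `budget_impact_result`.
#' @return ZAR per patient: year-1 net impact divided by the year-1
#'   treated population.
#' @export
per_patient_net_impact <- function(result) {
  stopifnot(inherits(result, "budget_impact_result"))
  if (result$years$treated_population[1L] <= 0) {
    stop("year-1 treated population is zero", call. = FALSE)
  }
  result$years$net_impact_zar[1L] / result$years$treated_population[1L]
}

#' Scale a budget impact by market-share uptake
#'
#' Applies a per-year uptake fraction to every avoided-cost and net-impact
#' delta (the intervention only reaches that share of the treated
#' population), recomputing the cumulative impact. The per-patient figure
#' is left on the uptake population basis, i.e. scaled like the deltas.
#'
#' @param result a `budget_impact_result`.
#' @param shares numeric vector of per-year uptake fractions in `[0, 1]`,
#'   one per model year.
#' @return A scaled `budget_impact_result`.
#' @export
#' @examples
#' cfg <- default_config()
#' bi <- budget_impact(scenario_costs(cfg, "standard_of_care"),
#'                     scenario_costs(cfg, "mydiacare"))
#' ms <- market_share_scenario(bi, cfg$market_shares)
#' ms$years$net_impact_zar[1] / 1e6  # ~530 million ZAR at 2% uptake
market_share_scenario <- function(result, shares) {
  stopifnot(inherits(result, "budget_impact_result"))
  ny <- nrow(result$years)
  if (length(shares) != ny) {
    stop("need one market share per model year (", ny, "), got ",
         length(shares), call. = FALSE)
  }
  if (any(shares < 0 | shares > 1)) {
    stop("market shares must lie in [0, 1], got ",
         shares[which(shares < 0 | shares > 1)[1L]], call. = FALSE)
  }
  out <- result
  sc <- function(m) m * rep(shares, each = nrow(m))
  out$events_avoided <- sc(result$events_avoided)
  out$costs_avoided <- sc(result$costs_avoided)
  out$years$complication_cost_avoided_zar <-
    result$years$complication_cost_avoided_zar * shares
  out$years$monitoring_cost_delta_zar <-
    result$years$monitoring_cost_delta_zar * shares
  out$years$net_impact_zar <- result$years$net_impact_zar * shares
  out$cumulative_net_impact_zar <- sum(out$years$net_impact_zar)
  out$per_patient_year1_zar <- out$years$net_impact_zar[1L] /
    out$years$treated_population[1L]
  out
}

#' Run the default two-scenario comparison
#'
#' Convenience wrapper: standard of care versus MyDiaCare on the packaged
#' (or supplied) configuration.
#'
#' @param config a `diabudget_config`.
#' @return A list with `without`, `with` (`scenario_result`s) and `impact`
#'   (`budget_impact_result`).
#' @export
run_budget_model <- function(config = default_config()) {
  without <- scenario_costs(config, "standard_of_care")
  with_ <- scenario_costs(config, "mydiacare")
  list(without = without, with = with_,
       impact = budget_impact(without, with_))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario cost projection:", x$cohort, "\n")
  df <- x$years
  df$complication_cost_zar <- round(df$complication_cost_zar)
  df$monitoring_cost_zar <- round(df$monitoring_cost_zar)
  df$total_cost_zar <- round(df$total_cost_zar)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.budget_impact_result <- function(x, ...) {
  cat("Budget impact (without - with), ZAR\n")
  df <- x$years
  for (col in c("complication_cost_avoided_zar", "monitoring_cost_delta_zar",
                "net_impact_zar")) {
    df[[col]] <- round(df[[col]])
  }
  print(df, row.names = FALSE)
  cat(sprintf("Cumulative net impact: %.0f ZAR\n",
              x$cumulative_net_impact_zar))
  cat(sprintf("Year-1 net impact per treated patient: %.0f ZAR\n",
              x$per_patient_year1_zar))
  invisible(x)
}
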