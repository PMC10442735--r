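# ---------------------------------------------------------------------------
# One-way deterministic sensitivity analysis (tornado data) and the named
# alternative scenarios.
# ---------------------------------------------------------------------------

#' Names of the parameters varied in the default sensitivity analysis
#'
#' The default set covers every scalar input a payer would question: the
#' seven complication unit costs, the seven baseline incidences, the four
#' cohort HbA1c levels, the year-1 prevalence, and the two per-patient
#' monitoring costs.
#'
#' @param config a `diabudget_config`.
#' @return Character vector of parameter names accepted by
#'   [set_model_parameter()] and [one_way_dsa()].
#' @export
dsa_parameters <- function(config = default_config()) {
  cp <- config$complications
  co <- config$cohorts
  mo <- config$monitoring
  c(paste0("cost_", cp$name),
    paste0("incidence_", cp$name),
    paste0("hba1c_baseline_", co$label),
    paste0("hba1c_6mo_", co$label),
    "prevalence_year1",
    paste0("monitoring_", mo$scenario))
}

#' Read a scalar model parameter by name
#' @param config a `diabudget_config`.
#' @param name one of [dsa_parameters()].
#' @return The parameter value.
#' @export
get_model_parameter <- function(config, name) {
  .param_accessor(config, name)$get()
}

#' Set a scalar model parameter by name
#' @param config a `diabudget_config`.
#' @param name one of [dsa_parameters()].
#' @param value new value.
#' @return A modified (revalidated) configuration.
#' @export
set_model_parameter <- function(config, name, value) {
  cfg <- .param_accessor(config, name)$set(value)
  validate_model_config(cfg)
  cfg
}

.param_accessor <- function(config, name) {
  cp <- config$complications
  co <- config$cohorts
  mo <- config$monitoring
  mk <- function(get, set) list(get = get, set = set)

  for (m in seq_len(nrow(cp))) {
    if (name == paste0("cost_", cp$name[m])) {
      return(mk(function() cp$cost_2021_zar[m], function(v) {
        config$complications$cost_2021_zar[m] <- v
        config
      }))
    }
    if (name == paste0("incidence_", cp$name[m])) {
      return(mk(function() cp$baseline_incidence_fraction[m], function(v) {
        config$complications$baseline_incidence_fraction[m] <- v
        config
      }))
    }
  }
  for (i in seq_len(nrow(co))) {
    if (name == paste0("hba1c_baseline_", co$label[i])) {
      return(mk(function() co$hba1c_baseline_percent[i], function(v) {
        config$cohorts$hba1c_baseline_percent[i] <- v
        config
      }))
    }
    if (name == paste0("hba1c_6mo_", co$label[i])) {
      return(mk(function() co$hba1c_6mo_percent[i], function(v) {
        config$cohorts$hba1c_6mo_percent[i] <- v
        config
      }))
    }
  }
  if (name == "prevalence_year1") {
    return(mk(function() config$population$prevalence[1L], function(v) {
      config$population$prevalence[1L] <- v
      config
    }))
  }
  for (j in seq_len(nrow(mo))) {
    if (name == paste0("monitoring_", mo$scenario[j])) {
      return(mk(function() mo$annual_cost_per_patient_zar[j], function(v) {
        config$monitoring$annual_cost_per_patient_zar[j] <- v
        config
      }))
    }
  }
  stop("unknown parameter '", name, "'; valid names are: ",
       paste(dsa_parameters(config), collapse = ", "), call. = FALSE)
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' For each named parameter, rebuilds the full model with the parameter at
#' `value * (1 - variance)` and `value * (1 + variance)` (all other inputs
#' held at base case) and records the year-1 net budget impact per treated
#' patient. HbA1c levels are varied multiplicatively like every other
#' parameter, under the single uniform variance.
#'
#' @param config a `diabudget_config`.
#' @param parameters character vector of parameter names; defaults to the
#'   full [dsa_parameters()] set.
#' @param variance symmetric relative variation (default 0.10, i.e. ±10%).
#' @param outcome function `config -> numeric scalar`; defaults to the
#'   year-1 net budget impact per treated patient.
#' @return A data frame, one row per parameter, sorted by descending output
#'   range (tornado order): `parameter`, `base_value`, `low_value`,
#'   `high_value`, `output_base`, `output_low`, `output_high`, `range`.
#' @export
#' @examples
#' dsa <- one_way_dsa(default_config(),
#'                    parameters = c("cost_nephropathy",
#'                                   "hba1c_6mo_mydiacare"))
#' dsa$parameter[1]  # the more influential of the two
one_way_dsa <- function(config = default_config(),
                        parameters = dsa_parameters(config),
                        variance = 0.10,
                        outcome = function(cfg)
                          per_patient_net_impact(run_budget_model(cfg)$impact)) {
  validate_model_config(config)
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  base_out <- outcome(config)
  rows <- lapply(parameters, function(p) {
    base <- get_model_parameter(config, p)
    low <- base * (1 - variance)
    high <- base * (1 + variance)
    out_low <- outcome(set_model_parameter(config, p, low))
    out_high <- outcome(set_model_parameter(config, p, high))
    data.frame(parameter = p, base_value = base, low_value = low,
               high_value = high, output_base = base_out,
               output_low = out_low, output_high = out_high,
               range = abs(out_high - out_low),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$range, res$parameter), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Equal-baseline alternative scenario
#'
#' Removes the baseline imbalance between the two cohorts: the
#' standard-of-care cohort is pinned at the MyDiaCare baseline HbA1c for
#' both timepoints (7.8%/7.8% under the defaults, i.e. no improvement),
#' while the MyDiaCare cohort keeps its observed trajectory (7.8% to
#' 7.2%). The full budget model is then rerun, so the remaining impact is
#' attributable to the HbA1c change alone.
#'
#' @param config a `diabudget_config`.
#' @return A `budget_impact_result`.
#' @export
equal_baseline_scenario <- function(config = default_config()) {
  validate_model_config(config)
  base <- get_model_parameter(config, "hba1c_baseline_mydiacare")
  cfg <- set_model_parameter(config, "hba1c_baseline_standard_of_care", base)
  cfg <- set_model_parameter(cfg, "hba1c_6mo_standard_of_care", base)
  run_budget_model(cfg)$impact
}
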