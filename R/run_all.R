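# ---------------------------------------------------------------------------
# Single entry point: runs the budget engine, sensitivity analysis and
# (optionally) synthetic cohort generation + clinical pipeline, and writes
# every CSV report plus a machine-readable JSON summary and a run
# manifest. `scripts/` wraps this in thin Rscript front-ends; the exported
# functions are the supported interface.
# ---------------------------------------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis and write all reports
#'
#' Executes the budget model (both scenarios), the budget impact, the
#' equal-baseline and market-share scenarios, the one-way sensitivity
#' analysis, and — when a cohort spec is supplied — synthetic cohort
#' generation plus the clinical outcome pipeline. Writes CSV tables, a
#' JSON summary of the headline quantities, and a run manifest.
#'
#' @param config a `diabudget_config`, a path to a JSON configuration, or
#'   `NULL` for the packaged defaults.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the synthetic cohort.
#' @param cohort a `cohort_spec`, or `NULL` to skip the clinical stage.
#' @param variance relative variation for the sensitivity analysis.
#' @return The run manifest (list with `timestamp`, `config_hash`, `seed`,
#'   `package_version`, `files`), invisibly. Also written as
#'   `manifest.json`.
#' @export
run_full_analysis <- function(config = NULL, out_dir, seed = 1L,
                              cohort = cohort_spec(), variance = 0.10) {
  cfg <- .stage("configuration", {
    if (is.null(config)) {
      default_config()
    } else if (is.character(config)) {
      load_model_config(config)
    } else {
      validate_model_config(config)
      config
    }
  })
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  model <- .stage("budget_engine", run_budget_model(cfg))
  bi <- model$impact
  eq <- .stage("sensitivity", equal_baseline_scenario(cfg))
  ms <- .stage("budget_engine", market_share_scenario(bi, cfg$market_shares))
  dsa <- .stage("sensitivity", one_way_dsa(cfg, variance = variance))

  .stage("reports", {
    sc <- rbind(cbind(scenario = model$without$cohort, model$without$years),
                cbind(scenario = model$with$cohort, model$with$years))
    emit(sc, "scenario_costs.csv")
    emit(bi$years, "budget_impact.csv")
    emit(data.frame(complication = rownames(bi$events_avoided),
                    round(bi$events_avoided / 1e3, 3)),
         "events_avoided_thousands.csv")
    emit(data.frame(complication = rownames(bi$costs_avoided),
                    round(bi$costs_avoided / 1e6, 1)),
         "costs_avoided_millions.csv")
    emit(adjusted_incidence_table(cfg), "adjusted_incidences.csv")
    emit(parameter_audit(cfg), "parameter_audit.csv")
    emit(dsa, "tornado.csv")
  })

  clinical <- NULL
  if (!is.null(cohort)) {
    clinical <- .stage("clinical_pipeline", {
      coh <- generate_cohort(cohort, seed = seed)
      paths <- write_cohort(coh, out_dir)
      files <- c(files, unname(paths))
      s <- cohort_summary(coh)
      emit(data.frame(
        statistic = c("n", "n_type1", "n_type2", "n_paired", "n_missing",
                      "change_mean", "change_sd", "change_median",
                      "change_q1", "change_q3",
                      "prop_relevant_decrease",
                      "mean_overall_adherence_percent",
                      "prop_adherence_above_70"),
        value = c(s$n, s$n_type1, s$n_type2, s$change$n_paired,
                  s$change$n_missing, s$change$mean, s$change$sd,
                  s$change$median, s$change$q1, s$change$q3,
                  s$change$prop_relevant_decrease,
                  s$adherence$mean_overall_percent,
                  s$adherence$prop_above_70)),
        "clinical_summary.csv")
      emit(s$bands, "hba1c_bands.csv")
      s
    })
  }

  summary <- list(
    year1 = list(
      treated_population = bi$years$treated_population[1L],
      total_cost_without_zar = model$without$years$total_cost_zar[1L],
      total_cost_with_zar = model$with$years$total_cost_zar[1L],
      complication_cost_without_zar =
        model$without$years$complication_cost_zar[1L],
      complication_cost_with_zar =
        model$with$years$complication_cost_zar[1L],
      monitoring_cost_without_zar =
        model$without$years$monitoring_cost_zar[1L],
      monitoring_cost_with_zar = model$with$years$monitoring_cost_zar[1L],
      complication_cost_avoided_zar =
        bi$years$complication_cost_avoided_zar[1L],
      net_impact_zar = bi$years$net_impact_zar[1L],
      per_patient_net_impact_zar = per_patient_net_impact(bi)
    ),
    cumulative_net_impact_zar = bi$cumulative_net_impact_zar,
    equal_baseline = list(
      year1_net_impact_zar = eq$years$net_impact_zar[1L],
      per_patient_net_impact_zar = per_patient_net_impact(eq)
    ),
    market_share = list(
      shares = cfg$market_shares,
      year1_net_impact_zar = ms$years$net_impact_zar[1L],
      cumulative_net_impact_zar = ms$cumulative_net_impact_zar
    ),
    tornado_top = dsa$parameter[seq_len(min(5L, nrow(dsa)))]
  )
  if (!is.null(clinical)) {
    summary$clinical <- list(
      n = clinical$n,
      n_paired = clinical$change$n_paired,
      change_mean = clinical$change$mean,
      change_sd = clinical$change$sd,
      mean_overall_adherence_percent =
        clinical$adherence$mean_overall_percent
    )
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, summary_path)

  cfg_tmp <- tempfile(fileext = ".json")
  save_model_config(cfg, cfg_tmp)
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(cfg_tmp)),
    seed = seed,
    package_version =
      as.character(utils::packageVersion("diabudget")),
    files = basename(files)
  )
  unlink(cfg_tmp)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
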