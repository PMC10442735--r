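# ---------------------------------------------------------------------------
# Model configuration: constants, validation, medical-inflation adjustment.
#
# All monetary values are ZAR; HbA1c values are percent; incidences and
# risk increments are dimensionless annual fractions. Monetary arithmetic
# is double precision throughout; rounding to whole ZAR happens only in
# report writers.
# ---------------------------------------------------------------------------

#' Default model configuration
#'
#' Builds the packaged model configuration: HbA1c threshold risk rules for
#' macrovascular and microvascular complications, the seven complication
#' parameters (annual baseline incidence, source cost, 2021 unit cost), the
#' two scenario cohorts (standard of care and MyDiaCare), the five-year
#' private-sector population projection, per-patient annual monitoring
#' costs, a medical-inflation table, and market-share uptake fractions.
#'
#' Risk rules: the risk of a macrovascular event rises by 38% for every 1%
#' of HbA1c above 7.0%; microvascular risk rises by 40% per 1% above 6.5%;
#' below the thresholds risk is flat. Complication incidences and unit
#' costs are published South African private-sector values. Monitoring
#' costs are not published per item; the packaged per-patient values are
#' calibrated so that scenario totals over the year-1 treated population
#' (371,528 patients) equal 2.5 billion ZAR (standard of care) and 3.6
#' billion ZAR (with MyDiaCare), and are flagged `CALIBRATED` in the audit
#' table. The annual medical-inflation rates are back-derived from the
#' published source-cost / 2021-cost pairs (the underlying Statistics South
#' Africa series is not reproduced in the source material), so they too are
#' flagged `CALIBRATED`.
#'
#' @return A list of class `diabudget_config` with components `settings`,
#'   `risk_rules`, `complications`, `inflation`, `cohorts`, `population`,
#'   `monitoring` and `market_shares`.
#' @export
#' @examples
#' cfg <- default_config()
#' nrow(cfg$complications)  # 7
default_config <- function() {
  # Inflation rates back-derived from anchor cost pairs:
  #   2021 rate from the amputation pair (2020 source year),
  #   2020 rate from the stroke pair (2019 source year),
  #   a constant 2015-2019 rate from the myocardial-infarction pair
  #   (2014 source year).
  r2021 <- 339589 / 323418 - 1
  f2019 <- 38245 / 34722                 # compounded 2019 -> 2021
  r2020 <- f2019 / (1 + r2021) - 1
  f2014 <- 65025 / 43415                 # compounded 2014 -> 2021
  r1519 <- (f2014 / f2019)^(1 / 5) - 1

  cfg <- list(
    settings = list(
      horizon_years = 5L,
      cost_year = 2021L,
      currency = "ZAR",
      usd_per_zar = 0.053
    ),
    risk_rules = data.frame(
      complication_class = c("macrovascular", "microvascular"),
      threshold_percent = c(7.0, 6.5),
      increment_per_point_fraction = c(0.38, 0.40),
      stringsAsFactors = FALSE
    ),
    complications = data.frame(
      name = c("myocardial_infarction", "stroke", "cardiovascular_disease",
               "nephropathy", "retinopathy", "foot_ulcers_diabetic_foot",
               "amputations"),
      complication_class = c("macrovascular", "macrovascular",
                             "macrovascular", "microvascular",
                             "microvascular", "microvascular",
                             "microvascular"),
      baseline_incidence_fraction = c(0.06, 0.04, 0.17, 0.25, 0.15, 0.13,
                                      0.03),
      source_cost_zar = c(43415, 34722, 21598, 503399, 3973, 83333, 323418),
      source_cost_year = c(2014L, 2019L, 2019L, 2019L, 2019L, 2021L, 2020L),
      cost_2021_zar = c(65025, 38245, 23789, 554469, 4376, 83333, 339589),
      stringsAsFactors = FALSE
    ),
    inflation = data.frame(
      year = 2015:2021,
      rate_fraction = c(rep(r1519, 5), r2020, r2021)
    ),
    cohorts = data.frame(
      label = c("standard_of_care", "mydiacare"),
      hba1c_baseline_percent = c(9.0, 7.8),
      hba1c_6mo_percent = c(8.2, 7.2),
      stringsAsFactors = FALSE
    ),
    population = data.frame(
      year = 1:5,
      prevalence = c(328118, 368295, 408454, 448603, 488752),
      incidence = c(43410, 43744, 44087, 44439, 44800)
    ),
    monitoring = data.frame(
      scenario = c("standard_of_care", "mydiacare"),
      annual_cost_per_patient_zar =
        c(2.5e9, 3.6e9) / (328118 + 43410),
      stringsAsFactors = FALSE
    ),
    market_shares = c(0.02, 0.03, 0.04, 0.05, 0.06)
  )
  class(cfg) <- "diabudget_config"
  validate_model_config(cfg)
}

#' Validate a model configuration
#'
#' Checks every structural and numerical invariant of the configuration:
#' required blocks present, exactly one risk rule per complication class,
#' incidences in \[0, 1\], non-negative costs, HbA1c levels in \[4, 20\],
#' exactly five projection years with positive counts, inflation rates
#' above -1, and market shares in \[0, 1\].
#'
#' @param config a configuration list as produced by [default_config()] or
#'   [load_model_config()].
#' @return The validated configuration, invisibly classed
#'   `diabudget_config`. Errors name the offending field or value.
#' @export
validate_model_config <- function(config) {
  required <- c("settings", "risk_rules", "complications", "inflation",
                "cohorts", "population", "monitoring", "market_shares")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0L) {
    stop("configuration error: missing required block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  rr <- config$risk_rules
  need_rr <- c("complication_class", "threshold_percent",
               "increment_per_point_fraction")
  .require_fields(rr, need_rr, "risk_rules")
  if (!setequal(rr$complication_class, c("macrovascular", "microvascular")) ||
      anyDuplicated(rr$complication_class)) {
    stop("validation error: risk_rules must contain exactly one rule per ",
         "complication class (macrovascular, microvascular)", call. = FALSE)
  }
  if (any(rr$threshold_percent <= 0)) {
    stop("validation error: risk rule threshold must be > 0, got ",
         min(rr$threshold_percent), call. = FALSE)
  }
  if (any(rr$increment_per_point_fraction < 0)) {
    stop("validation error: risk increment must be >= 0, got ",
         min(rr$increment_per_point_fraction), call. = FALSE)
  }

  cp <- config$complications
  need_cp <- c("name", "complication_class", "baseline_incidence_fraction",
               "source_cost_zar", "source_cost_year", "cost_2021_zar")
  .require_fields(cp, need_cp, "complications")
  if (anyDuplicated(cp$name)) {
    stop("validation error: duplicated complication name", call. = FALSE)
  }
  bad_class <- setdiff(cp$complication_class, rr$complication_class)
  if (length(bad_class) > 0L) {
    stop("validation error: unknown complication class: ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  bad_inc <- cp$baseline_incidence_fraction
  if (any(bad_inc < 0 | bad_inc > 1)) {
    stop("validation error: baseline_incidence_fraction must lie in [0, 1], ",
         "got ", bad_inc[which(bad_inc < 0 | bad_inc > 1)[1L]],
         call. = FALSE)
  }
  if (any(cp$source_cost_zar < 0) || any(cp$cost_2021_zar < 0)) {
    stop("validation error: complication costs must be >= 0", call. = FALSE)
  }

  co <- config$cohorts
  .require_fields(co, c("label", "hba1c_baseline_percent",
                        "hba1c_6mo_percent"), "cohorts")
  hb <- c(co$hba1c_baseline_percent, co$hba1c_6mo_percent)
  if (any(hb < 4 | hb > 20)) {
    stop("validation error: cohort HbA1c must lie in [4, 20] percent, got ",
         hb[which(hb < 4 | hb > 20)[1L]], call. = FALSE)
  }

  pp <- config$population
  .require_fields(pp, c("year", "prevalence", "incidence"), "population")
  if (nrow(pp) != 5L || !identical(as.integer(pp$year), 1:5)) {
    stop("validation error: population projection must cover model years ",
         "1..5 exactly", call. = FALSE)
  }
  if (any(pp$prevalence <= 0) || any(pp$incidence <= 0)) {
    stop("validation error: population counts must be > 0", call. = FALSE)
  }

  mo <- config$monitoring
  .require_fields(mo, c("scenario", "annual_cost_per_patient_zar"),
                  "monitoring")
  if (any(mo$annual_cost_per_patient_zar < 0)) {
    stop("validation error: monitoring cost must be >= 0", call. = FALSE)
  }

  it <- config$inflation
  .require_fields(it, c("year", "rate_fraction"), "inflation")
  if (any(it$rate_fraction <= -1)) {
    stop("validation error: inflation rate must be > -1", call. = FALSE)
  }

  ms <- config$market_shares
  if (any(ms < 0 | ms > 1)) {
    stop("validation error: market shares must lie in [0, 1], got ",
         ms[which(ms < 0 | ms > 1)[1L]], call. = FALSE)
  }

  class(config) <- "diabudget_config"
  invisible(config)
}

.require_fields <- function(df, fields, block) {
  miss <- setdiff(fields, names(df))
  if (length(miss) > 0L) {
    stop("configuration error: block '", block, "' is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a model configuration from a JSON file
#'
#' Reads a JSON configuration and fills every omitted block from the
#' packaged defaults ([default_config()]), so a file may override only the
#' pieces under study. The merged configuration is fully validated.
#'
#' @param path path to a JSON configuration file, or `NULL` for the pure
#'   defaults.
#' @return A validated `diabudget_config`.
#' @seealso [save_model_config()] for the inverse operation.
#' @export
load_model_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("configuration error: file not found: ", path, call. = FALSE)
    }
    user <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    for (block in names(user)) {
      value <- user[[block]]
      if (block == "settings" && is.list(value)) {
        cfg$settings[names(value)] <- value
      } else {
        cfg[[block]] <- value
      }
    }
    # jsonlite returns plain numerics; restore integer columns
    if (!is.null(cfg$population$year)) {
      cfg$population$year <- as.integer(cfg$population$year)
    }
    if (!is.null(cfg$complications$source_cost_year)) {
      cfg$complications$source_cost_year <-
        as.integer(cfg$complications$source_cost_year)
    }
    cfg$settings$horizon_years <- as.integer(cfg$settings$horizon_years)
    cfg$settings$cost_year <- as.integer(cfg$settings$cost_year)
    if (!is.null(cfg$inflation$year)) {
      cfg$inflation$year <- as.integer(cfg$inflation$year)
    }
  }
  class(cfg) <- "diabudget_config"
  validate_model_config(cfg)
  cfg
}

#' Write a model configuration to JSON
#'
#' @param config a validated `diabudget_config`.
#' @param path output file path.
#' @return `path`, invisibly. Reloading the file with
#'   [load_model_config()] yields a value-identical configuration.
#' @export
save_model_config <- function(config, path) {
  validate_model_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Inflate a cost between calendar years
#'
#' Applies compounded medical inflation over the half-open interval
#' `(from_year, to_year]`: the returned amount is
#' `amount * prod(1 + rate[y])` for `y` in `from_year + 1, ..., to_year`.
#' `from_year == to_year` returns the amount unchanged.
#'
#' @param amount cost in ZAR.
#' @param from_year calendar year the amount is expressed in.
#' @param to_year target calendar year (`>= from_year`).
#' @param table inflation table: a data frame with columns `year` and
#'   `rate_fraction`; defaults to the packaged table.
#' @return The inflated amount in ZAR (double; not rounded).
#' @export
#' @examples
#' inflate_cost(83333, 2021, 2021)  # unchanged
#' round(inflate_cost(34722, 2019, 2021))  # 38245
inflate_cost <- function(amount, from_year, to_year,
                         table = default_config()$inflation) {
  if (to_year < from_year) {
    stop("inflate_cost: to_year (", to_year, ") must be >= from_year (",
         from_year, ")", call. = FALSE)
  }
  if (from_year == to_year) return(amount)
  years <- seq(from_year + 1L, to_year)
  idx <- match(years, table$year)
  if (anyNA(idx)) {
    stop("inflate_cost: year ", years[which(is.na(idx))[1L]],
         " not covered by the inflation table", call. = FALSE)
  }
  amount * prod(1 + table$rate_fraction[idx])
}

#' Parameter audit table
#'
#' One row per model parameter with its value, units, and provenance:
#' `PAPER` for values taken directly from published tables and text,
#' `CALIBRATED` for values back-derived from published aggregates (the
#' per-patient monitoring costs and the annual inflation rates).
#'
#' @param config a `diabudget_config`.
#' @return A data frame with columns `name`, `value`, `units`, `source`.
#' @export
parameter_audit <- function(config = default_config()) {
  validate_model_config(config)
  cp <- config$complications
  rr <- config$risk_rules
  co <- config$cohorts
  pp <- config$population
  mo <- config$monitoring
  it <- config$inflation
  rows <- rbind(
    data.frame(name = paste0("risk_threshold_", rr$complication_class),
               value = rr$threshold_percent, units = "percent HbA1c",
               source = "PAPER"),
    data.frame(name = paste0("risk_increment_", rr$complication_class),
               value = rr$increment_per_point_fraction,
               units = "fraction per 1% HbA1c", source = "PAPER"),
    data.frame(name = paste0("incidence_", cp$name),
               value = cp$baseline_incidence_fraction,
               units = "annual fraction", source = "PAPER"),
    data.frame(name = paste0("cost_2021_", cp$name),
               value = cp$cost_2021_zar, units = "ZAR per event",
               source = "PAPER"),
    data.frame(name = paste0("hba1c_baseline_", co$label),
               value = co$hba1c_baseline_percent, units = "percent",
               source = "PAPER"),
    data.frame(name = paste0("hba1c_6mo_", co$label),
               value = co$hba1c_6mo_percent, units = "percent",
               source = "PAPER"),
    data.frame(name = paste0("prevalence_year", pp$year),
               value = pp$prevalence, units = "patients", source = "PAPER"),
    data.frame(name = paste0("incident_cases_year", pp$year),
               value = pp$incidence, units = "patients", source = "PAPER"),
    data.frame(name = paste0("monitoring_cost_", mo$scenario),
               value = mo$annual_cost_per_patient_zar,
               units = "ZAR per patient per year", source = "CALIBRATED"),
    data.frame(name = paste0("inflation_rate_", it$year),
               value = it$rate_fraction, units = "annual fraction",
               source = "CALIBRATED")
  )
  rownames(rows) <- NULL
  rows
}
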