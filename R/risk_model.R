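# ---------------------------------------------------------------------------
# HbA1c -> relative risk -> adjusted annual complication incidence.
#
# The threshold rules are additive on a 0.1% HbA1c grid: each 0.1% of
# excess HbA1c above the class threshold adds increment/10 to the
# multiplier (3.8% per 0.1% for macrovascular events, 4.0% for
# microvascular events). Summing the 0.1 steps is algebraically identical
# to the linear closed form 1 + increment * excess once the excess has been
# snapped to the 0.1 grid; the closed form is what is evaluated here, and
# the step-summing formulation is retained as an independent oracle in the
# test suite.
# ---------------------------------------------------------------------------

#' Relative risk multiplier for a given HbA1c level
#'
#' Computes `1 + increment * max(0, hba1c - threshold)` with the excess
#' HbA1c rounded to the nearest 0.1 percentage point (ties rounded up)
#' before scaling, matching the 0.1%-increment formulation of the risk
#' rule. At or below the threshold the multiplier is exactly 1.
#'
#' @param hba1c HbA1c level(s) in percent (vectorised).
#' @param rule a single risk rule: one row of `config$risk_rules` (or any
#'   list with `threshold_percent` and `increment_per_point_fraction`).
#' @return Dimensionless multiplier(s) `>= 1`.
#' @export
#' @examples
#' cfg <- default_config()
#' macro <- cfg$risk_rules[cfg$risk_rules$complication_class ==
#'                           "macrovascular", ]
#' risk_multiplier(8.2, macro)  # 1.456
risk_multiplier <- function(hba1c, rule) {
  stopifnot(is.numeric(hba1c),
            rule$threshold_percent > 0,
            rule$increment_per_point_fraction >= 0)
  excess <- pmax(0, hba1c - rule$threshold_percent)
  # nearest 0.1 with ties up; the epsilon absorbs binary representation
  # error in differences like 8.2 - 7.0
  steps <- floor(excess * 10 + 0.5 + 1e-9)
  1 + rule$increment_per_point_fraction * steps / 10
}

#' Look up the risk rule for a complication class
#' @param config a `diabudget_config`.
#' @param complication_class `"macrovascular"` or `"microvascular"`.
#' @return A one-row data frame.
#' @export
get_risk_rule <- function(config, complication_class) {
  rr <- config$risk_rules
  i <- which(rr$complication_class == complication_class)
  if (length(i) != 1L) {
    stop("no risk rule for complication class '", complication_class, "'",
         call. = FALSE)
  }
  rr[i, , drop = FALSE]
}

#' HbA1c-adjusted annual complication incidence
#'
#' Scales a complication's baseline annual incidence by the relative risk
#' multiplier of its class at the given HbA1c level, capping the result at
#' 1 (it is a probability). At or below the class threshold the adjusted
#' incidence equals the baseline incidence.
#'
#' @param comp one row of `config$complications`.
#' @param hba1c HbA1c level(s) in percent.
#' @param rules the `risk_rules` data frame (both classes).
#' @return Annual incidence fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' cfg <- default_config()
#' neph <- cfg$complications[cfg$complications$name == "nephropathy", ]
#' adjusted_incidence(neph, 9.0, cfg$risk_rules)  # 0.25 * 2.00 = 0.50
adjusted_incidence <- function(comp, hba1c, rules) {
  i <- which(rules$complication_class == comp$complication_class)
  if (length(i) != 1L) {
    stop("unknown complication class '", comp$complication_class, "'",
         call. = FALSE)
  }
  pmin(1, comp$baseline_incidence_fraction *
         risk_multiplier(hba1c, rules[i, , drop = FALSE]))
}

#' Annual incidence for a model year under a cohort's HbA1c trajectory
#'
#' The cohort is characterised by its mean HbA1c at baseline and at 6
#' months; beyond 6 months the level is assumed stable. Year 1 therefore
#' spends its first half at the baseline level and its second half at the
#' 6-month level, and its incidence is the arithmetic mean of the adjusted
#' incidences at the two levels. Years 2-5 use the 6-month level alone.
#'
#' @param comp one row of `config$complications`.
#' @param cohort one row of `config$cohorts` (fields
#'   `hba1c_baseline_percent`, `hba1c_6mo_percent`).
#' @param year model year in 1..5.
#' @param rules the `risk_rules` data frame.
#' @return Annual incidence fraction.
#' @export
#' @examples
#' cfg <- default_config()
#' neph <- cfg$complications[cfg$complications$name == "nephropathy", ]
#' soc <- cfg$cohorts[cfg$cohorts$label == "standard_of_care", ]
#' year_incidence(neph, soc, 1, cfg$risk_rules)  # mean(0.50, 0.42) = 0.46
year_incidence <- function(comp, cohort, year, rules) {
  if (!(year %in% 1:5)) {
    stop("year must be in 1..5, got ", year, call. = FALSE)
  }
  at6 <- adjusted_incidence(comp, cohort$hba1c_6mo_percent, rules)
  if (year == 1L) {
    at0 <- adjusted_incidence(comp, cohort$hba1c_baseline_percent, rules)
    (at0 + at6) / 2
  } else {
    at6
  }
}

#' Adjusted-incidence table for all complications, cohorts and years
#'
#' @param config a `diabudget_config`.
#' @return A data frame with one row per complication x cohort x model
#'   year, with the HbA1c-adjusted annual incidence fraction.
#' @export
adjusted_incidence_table <- function(config = default_config()) {
  validate_model_config(config)
  cp <- config$complications
  co <- config$cohorts
  grid <- expand.grid(complication = cp$name, cohort = co$label,
                      year = 1:5, stringsAsFactors = FALSE)
  grid$incidence_fraction <- mapply(function(cname, clabel, yr) {
    year_incidence(cp[cp$name == cname, , drop = FALSE],
                   co[co$label == clabel, , drop = FALSE],
                   yr, config$risk_rules)
  }, grid$complication, grid$cohort, grid$year)
  grid[order(grid$cohort, grid$complication, grid$year), , drop = FALSE]
}
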