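#' One-way cost-driver sensitivity scenarios
#'
#' Sensitivity scenarios scale the health-care (including equipment) and
#' the productivity/leisure cost categories independently, typically over
#' +/-60%, and recompute the bootstrap summaries and acceptability curves.
#' Common random numbers are used across scenarios (the same resample
#' indices), so differences between scenario curves reflect only the cost
#' scaling, not Monte-Carlo noise.
#'
#' @name sensitivity
NULL

#' Define a sensitivity scenario
#'
#' @param healthcare_multiplier factor applied to health-care and
#'   equipment cost fields (> 0).
#' @param indirect_multiplier factor applied to productivity/leisure cost
#'   fields (> 0).
#' @param label scenario label; defaults to `"hc=<h>,ind=<i>"`.
#' @return An object of class `cea_scenario`.
#' @export
sensitivity_scenario <- function(healthcare_multiplier = 1,
                                 indirect_multiplier = 1,
                                 label = NULL) {
  if (healthcare_multiplier <= 0 || indirect_multiplier <= 0) {
    stop("scenario multipliers must be > 0", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("hc=%g,ind=%g", healthcare_multiplier,
                     indirect_multiplier)
  }
  structure(list(healthcare_multiplier = healthcare_multiplier,
                 indirect_multiplier = indirect_multiplier, label = label),
            class = "cea_scenario")
}

#' Grid of sensitivity scenarios
#'
#' Crossed grid of multipliers; the default spans +/-60% in both cost
#' categories.
#'
#' @param healthcare,indirect multiplier vectors.
#' @return A list of [sensitivity_scenario()] objects.
#' @export
scenario_grid <- function(healthcare = c(0.4, 1, 1.6),
                          indirect = c(0.4, 1, 1.6)) {
  out <- list()
  for (h in healthcare) for (i in indirect) {
    out[[length(out) + 1]] <- sensitivity_scenario(h, i)
  }
  out
}

#' Apply a sensitivity scenario to cost breakdowns
#'
#' Scales health-care + equipment fields by the health-care multiplier and
#' productivity/leisure fields by the indirect multiplier, then recomputes
#' the totals so the sum invariants hold again.
#'
#' @param breakdowns a `cea_costs` data frame from [total_cost()].
#' @param scenario a `cea_scenario`.
#' @return The scaled `cea_costs` data frame.
#' @export
apply_scenario <- function(breakdowns, scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  fields <- cost_fields()
  for (f in fields$healthcare) {
    breakdowns[[f]] <- breakdowns[[f]] * scenario$healthcare_multiplier
  }
  for (f in fields$productivity) {
    breakdowns[[f]] <- breakdowns[[f]] * scenario$indirect_multiplier
  }
  breakdowns$total_healthcare <-
    unname(rowSums(breakdowns[, fields$healthcare, drop = FALSE]))
  breakdowns$total_productivity <-
    unname(rowSums(breakdowns[, fields$productivity, drop = FALSE]))
  breakdowns$total <-
    breakdowns$total_healthcare + breakdowns$total_productivity
  breakdowns
}

#' Acceptability curves across sensitivity scenarios
#'
#' One CEAC per scenario for a given contrast, computed with common random
#' numbers: the same master seed means the same resample indices in every
#' scenario, so curve differences isolate the cost scaling.
#'
#' @inheritParams bootstrap_contrast
#' @param scenarios a list of [sensitivity_scenario()] objects (e.g. from
#'   [scenario_grid()]).
#' @param wtp_grid willingness-to-pay grid.
#' @param measure `"remission"` or `"qaly"`.
#' @return A long-format data frame with columns `scenario`,
#'   `healthcare_multiplier`, `indirect_multiplier`, `wtp`, `probability`.
#' @export
scenario_ceacs <- function(impsets, arm_a, arm_b, scenarios, B = 1000,
                           seed = 1, costs = default_unit_costs(),
                           horizon_years = 0.5,
                           wtp_grid = seq(0, 20000, by = 500),
                           measure = "remission") {
  out <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    draws <- bootstrap_contrast(impsets, arm_a, arm_b, B = B, seed = seed,
                                costs = costs,
                                horizon_years = horizon_years,
                                scenario = sc)
    cv <- ceac(draws, wtp_grid, measure)
    out[[i]] <- data.frame(scenario = sc$label,
                           healthcare_multiplier = sc$healthcare_multiplier,
                           indirect_multiplier = sc$indirect_multiplier,
                           wtp = cv$wtp, probability = cv$probability)
  }
  do.call(rbind, out)
}
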