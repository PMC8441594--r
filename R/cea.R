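#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost and effect of a comparator over a reference
#' strategy and classifies the result: an ICER when the comparator is both
#' costlier and more effective (or cheaper and less effective — the ratio is
#' then reported from the same quotient), `comparator_dominant` when it is
#' cheaper and more effective, `comparator_dominated` when costlier and less
#' effective, and `equal_effect` (no ratio) when the effect difference is
#' below 1e-12.
#'
#' @param ref,comp `arm_result` objects (or lists with `discounted_cost`,
#'   `discounted_qaly`).
#' @return List of class `cea_comparison` with `ref_cost`, `comp_cost`,
#'   `ref_qaly`, `comp_qaly`, `delta_cost`, `delta_qaly`, `status`, and
#'   `icer` (NA unless `status == "icer"`).
#' @export
compute_icer <- function(ref, comp) {
  dc <- comp$discounted_cost - ref$discounted_cost
  de <- comp$discounted_qaly - ref$discounted_qaly
  if (abs(de) < 1e-12) {
    status <- "equal_effect"; icer <- NA_real_
  } else if (dc < 0 && de > 0) {
    status <- "comparator_dominant"; icer <- NA_real_
  } else if (dc > 0 && de < 0) {
    status <- "comparator_dominated"; icer <- NA_real_
  } else {
    status <- "icer"; icer <- dc / de
  }
  structure(list(ref_cost = ref$discounted_cost,
                 comp_cost = comp$discounted_cost,
                 ref_qaly = ref$discounted_qaly,
                 comp_qaly = comp$discounted_qaly,
                 delta_cost = dc, delta_qaly = de,
                 status = status, icer = icer),
            class = "cea_comparison")
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`; positive iff the strategy is
#' cost-effective at the willingness-to-pay threshold.
#'
#' @param delta_cost Incremental cost (INT$).
#' @param delta_qaly Incremental effect (QALY).
#' @param wtp Willingness to pay (INT$/QALY), >= 0.
#' @return Net monetary benefit in INT$.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * delta_qaly - delta_cost
}

# Effective cycle count: the horizon, truncated where the life table's
# certain death at the terminal age makes further cycles vacuous.
.n_cycles <- function(p) {
  n <- p$horizon_years / p$cycle_years
  if (abs(n - round(n)) > 1e-9)
    stop("horizon_years must be a whole number of cycles")
  as.integer(round(n))
}

#' Run one extrapolation scenario for both arms
#'
#' Builds the scenario's effect schedule, runs control and intervention
#' arms through the cohort engine, and assembles the incremental
#' comparison. The schedule touches only the intervention arm, so control
#' results are identical across scenarios.
#'
#' @param config An `htncea_config` (see [default_config()]).
#' @param scenario "pessimistic", "intermediate" or "optimistic"; defaults
#'   to the config's scenario.
#' @param lt Life table.
#' @param followup Follow-up cost duration; see [accumulate_outcomes()].
#' @return List of class `scenario_results`: `scenario`, `control`,
#'   `intervention` (`arm_result`s), `comparison` (`cea_comparison`),
#'   `cost_effect_control`, `cost_effect_intervention` (per-arm INT$/QALY).
#' @export
run_scenario <- function(config, scenario = config$scenario, lt,
                         followup = c("first_year", "lifelong")) {
  followup <- match.arg(followup)
  p <- config$params
  sched <- build_effect_schedule(scenario, .n_cycles(p), p$rr_intervention)
  ctrl <- run_arm("control", p, sched, lt, followup)
  intv <- run_arm("intervention", p, sched, lt, followup)
  structure(list(scenario = scenario, control = ctrl, intervention = intv,
                 comparison = compute_icer(ctrl, intv),
                 cost_effect_control =
                   ctrl$discounted_cost / ctrl$discounted_qaly,
                 cost_effect_intervention =
                   intv$discounted_cost / intv$discounted_qaly),
            class = "scenario_results")
}

#' Run all three extrapolation scenarios
#'
#' @inheritParams run_scenario
#' @return Named list of `scenario_results` for pessimistic, intermediate
#'   and optimistic scenarios.
#' @export
run_all_scenarios <- function(config, lt,
                              followup = c("first_year", "lifelong")) {
  followup <- match.arg(followup)
  sc <- c("pessimistic", "intermediate", "optimistic")
  stats::setNames(lapply(sc, run_scenario, config = config, lt = lt,
                         followup = followup), sc)
}

#' Scenario results as a strategy-per-row table
#'
#' Machine twin of the published results table: two strategy rows per
#' scenario with costs, effects, increments, per-arm cost/effect ratio and
#' the ICER, at full precision.
#'
#' @param results List of `scenario_results`, as from [run_all_scenarios()].
#' @return data.frame with columns `Scenario`, `Strategy`, `Cost`,
#'   `IncrementalCost`, `Effect`, `IncrementalEffect`, `CostPerEffect`,
#'   `ICER`.
#' @export
results_table <- function(results) {
  if (inherits(results, "scenario_results")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    cmp <- r$comparison
    data.frame(
      Scenario = r$scenario,
      Strategy = c("usual_care", "multicomponent_intervention"),
      Cost = c(cmp$ref_cost, cmp$comp_cost),
      IncrementalCost = c(NA, cmp$delta_cost),
      Effect = c(cmp$ref_qaly, cmp$comp_qaly),
      IncrementalEffect = c(NA, cmp$delta_qaly),
      CostPerEffect = c(r$cost_effect_control, r$cost_effect_intervention),
      ICER = c(NA, cmp$icer))
  }))
}

#' Write a results table (or any export table) to CSV
#'
#' Full-precision serialisation; display rounding belongs to the caller.
#'
#' @param tab data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
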