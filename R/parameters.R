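#' Base-case model parameters
#'
#' Returns the full set of model inputs for the base-case analysis: per-cycle
#' costs in 2017 international dollars (INT$), six-month transition
#' probabilities, annual utility weights, the trial blood-pressure effect and
#' its relative-risk mapping, and the model's structural constants (start age
#' 55, 45-year horizon in 6-month cycles, 5% annual discount rate, 20%
#' ten-year-risk cutoff, INT$18 000/QALY willingness-to-pay threshold).
#'
#' `rr_intervention` is derived at full precision from the trial's net SBP
#' reduction via [rr_from_sbp_effect()]; all other values are the published
#' base case. `mortality_multiplier` (base 1) scales life-table mortality and
#' exists to support one-way sensitivity analysis of the mortality rate.
#'
#' @return A named list of class `htncea_params`. Costs are INT$ per event,
#'   per year, or per 6-month cycle as named; probabilities are per 6-month
#'   cycle except `risk_cutoff` (10-year); utilities are per year.
#' @export
#' @examples
#' p <- default_parameters()
#' p$c_event
#' p$horizon_years / p$cycle_years  # 90 cycles
default_parameters <- function() {
  p <- list(
    c_event           = 1732.47,  # INT$ per CVD event
    c_event_followup  = 300.00,   # INT$ per year, first post-event year
    c_hs_control      = 82.69,    # INT$ per 6-mo cycle
    c_hs_intervention = 105.30,   # INT$ per 6-mo cycle
    c_program         = 53.88,    # INT$ per 6-mo cycle, trial cycles only
    p_event_high      = 0.0267,   # per 6-mo cycle
    p_event_low       = 0.0058,   # per 6-mo cycle
    p_cvd_fatal       = 0.30,     # per event
    u_high            = 0.7963,
    u_low             = 0.8176,
    du_event          = -0.2775,  # utility decrement, first post-event year
    qaly_diff_trial   = 0.0420,   # QALY add-on, intervention arm, cycles 1-3
    prop_high         = 0.60,
    rr_per_10         = 0.80,     # RR of major CVD per 10 mm Hg SBP reduction
    delta_sbp         = -5.30,    # net SBP change, mm Hg (negative = reduction)
    discount_rate     = 0.05,     # annual
    start_age         = 55,
    horizon_years     = 45,
    cycle_years       = 0.5,
    risk_cutoff       = 0.20,     # 10-year risk
    wtp               = 18000,    # INT$/QALY
    ppp_rate          = 11.47,    # ARS per INT$
    mortality_multiplier = 1.0
  )
  p$rr_intervention <- rr_from_sbp_effect(p$delta_sbp, p$rr_per_10)
  class(p) <- "htncea_params"
  viol <- validate_parameters(p)
  if (length(viol)) stop("default parameters failed validation: ",
                         paste(viol, collapse = "; "))
  p
}

#' Uncertainty specification for every model parameter
#'
#' One row per parameter that carries an uncertainty range: base value, low
#' and high bounds (95% CI where published, otherwise +/-25% of base), the
#' distribution family used in probabilistic sensitivity analysis, and flags
#' saying whether the parameter enters the one-way (tornado) analysis and the
#' PSA. The QALY trial difference and the SBP effect are excluded from all
#' sensitivity analyses; the discount rate, start age, time horizon and
#' mortality multiplier are varied one-way only. The relative-risk row is
#' stored with ordered bounds (low 0.79, high 0.99) although it is
#' conventionally quoted high-to-low.
#'
#' @param p Model parameters, as from [default_parameters()]; supplies base
#'   values so that spec rows follow any overridden base case.
#' @return A data.frame with columns `name`, `base`, `low`, `high`, `dist`
#'   (one of beta/gamma/triangular/lognormal/none), `in_oneway`, `in_psa`.
#' @export
parameter_specs <- function(p = default_parameters()) {
  # published ranges; widened where an overridden base falls outside them
  spec <- function(name, base, low, high, dist, ow = TRUE, psa = dist != "none")
    data.frame(name = name, base = base, low = min(low, base),
               high = max(high, base), dist = dist,
               in_oneway = ow, in_psa = psa, stringsAsFactors = FALSE)
  out <- rbind(
    spec("c_event",           p$c_event,           1299.35, 2165.58, "gamma"),
    spec("c_event_followup",  p$c_event_followup,   225.00,  375.00, "gamma"),
    spec("c_hs_control",      p$c_hs_control,        62.02,  103.36, "gamma"),
    spec("c_program",         p$c_program,           40.41,   67.35, "gamma"),
    spec("c_hs_intervention", p$c_hs_intervention,   78.98,  131.63, "gamma"),
    spec("p_event_high",      p$p_event_high,        0.0201,  0.0334, "beta"),
    spec("p_event_low",       p$p_event_low,         0.0044,  0.0073, "beta"),
    spec("p_cvd_fatal",       p$p_cvd_fatal,         0.26,    0.33,   "triangular"),
    spec("u_high",            p$u_high,              0.5972,  0.9954, "beta"),
    spec("u_low",             p$u_low,               0.6132,  1.0000, "beta"),
    spec("du_event",          p$du_event,           -0.3469, -0.2081, "beta"),
    spec("prop_high",         p$prop_high,           0.45,    0.75,   "beta"),
    # RR bounds normalised low <= high; printed base 0.88 backs the PSA fit
    spec("rr_intervention",   0.88,                  0.79,    0.99,   "lognormal"),
    spec("discount_rate",     p$discount_rate,       0.01,    0.10,   "none"),
    spec("start_age",         p$start_age,           40,      70,     "none"),
    # +/-25% of 45 y, rounded outward to whole 6-month cycles
    spec("horizon_years",     p$horizon_years,       33.5,    56.5,   "none"),
    spec("mortality_multiplier", p$mortality_multiplier, 0.75, 1.25,  "none"),
    spec("qaly_diff_trial",   p$qaly_diff_trial, p$qaly_diff_trial,
         p$qaly_diff_trial, "none", ow = FALSE),
    spec("delta_sbp",         p$delta_sbp, p$delta_sbp, p$delta_sbp,
         "none", ow = FALSE)
  )
  stopifnot(all(out$low <= out$base + 1e-12), all(out$base <= out$high + 1e-12))
  out
}

#' Validate model parameters
#'
#' Checks every structural invariant: probabilities and utilities within
#' their ranges, non-negative costs, the low-risk utility at least the
#' high-risk utility, a positive cycle length dividing the horizon into a
#' whole number of cycles, and (when a life table is supplied) coverage of
#' the modelled age span.
#'
#' @param p Parameter list as from [default_parameters()].
#' @param life_table Optional life table (see [read_life_table()]); when
#'   given, the modelled ages must start within the table. Ages beyond the
#'   table's terminal age are treated as certain death, so a horizon that
#'   overshoots the table is not a violation.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_parameters <- function(p, life_table = NULL) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  probs <- c("p_event_high", "p_event_low", "p_cvd_fatal", "prop_high",
             "risk_cutoff", "discount_rate")
  for (nm in probs)
    chk(is.numeric(p[[nm]]) && p[[nm]] >= 0 && p[[nm]] <= 1,
        sprintf("%s: must be a probability in [0, 1]", nm))
  costs <- c("c_event", "c_event_followup", "c_hs_control",
             "c_hs_intervention", "c_program", "wtp")
  for (nm in costs)
    chk(is.numeric(p[[nm]]) && p[[nm]] >= 0, sprintf("%s: must be >= 0", nm))
  chk(p$u_high >= 0 && p$u_high <= 1, "u_high: must be in [0, 1]")
  chk(p$u_low >= 0 && p$u_low <= 1, "u_low: must be in [0, 1]")
  chk(p$u_low >= p$u_high, "u_low: must be >= u_high")
  chk(p$du_event <= 0, "du_event: must be <= 0 (a decrement)")
  chk(p$cycle_years > 0, "cycle_years: must be > 0")
  if (p$cycle_years > 0) {
    n_cyc <- p$horizon_years / p$cycle_years
    chk(abs(n_cyc - round(n_cyc)) < 1e-9,
        "horizon_years: must be a whole number of cycles of cycle_years")
  }
  chk(p$rr_per_10 > 0 && p$rr_per_10 <= 1, "rr_per_10: must be in (0, 1]")
  chk(p$rr_intervention > 0 && p$rr_intervention <= 1,
      "rr_intervention: must be in (0, 1]")
  chk(p$ppp_rate > 0, "ppp_rate: must be > 0")
  chk(p$mortality_multiplier > 0, "mortality_multiplier: must be > 0")
  chk(p$start_age >= 21 && p$start_age <= 100,
      "start_age: must be in [21, 100]")
  if (!is.null(life_table)) {
    chk(min(life_table$age) <= p$start_age,
        "start_age: below the life table's first age")
  }
  v
}

#' Convert Argentine pesos to international dollars
#'
#' @param amount Amount in ARS.
#' @param ppp_rate Purchasing-power-parity rate, ARS per INT$ (11.47 in 2017).
#' @return Amount in INT$.
#' @export
pesos_to_intl <- function(amount, ppp_rate = 11.47) {
  if (!is.numeric(ppp_rate) || ppp_rate <= 0)
    stop("ppp_rate must be > 0")
  amount / ppp_rate
}

.config_extra_keys <- c("scenario", "psa_iterations", "seed", "wtp_grid",
                        "life_table_path")

#' Default analysis configuration
#'
#' @param params Model parameters.
#' @return A list of class `htncea_config` with elements `params`, `specs`,
#'   `scenario` (intermediate = base case), `psa_iterations` (5000), `seed`,
#'   `wtp_grid` and `life_table_path` (empty = use the bundled synthetic
#'   Gompertz-Makeham table).
#' @export
default_config <- function(params = default_parameters()) {
  cfg <- list(params = params,
              specs = parameter_specs(params),
              scenario = "intermediate",
              psa_iterations = 5000,
              seed = 1L,
              wtp_grid = seq(0, 50000, by = 500),
              life_table_path = "")
  class(cfg) <- "htncea_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' The file is a flat key/value document. Recognised keys are the
#' [default_parameters()] field names plus `scenario`, `psa_iterations`,
#' `seed`, `wtp_grid` and `life_table_path`; any key omitted falls back to
#' the default. Unknown keys are hard errors so that a typo cannot silently
#' run the base case. `rr_intervention` is re-derived from `delta_sbp` and
#' `rr_per_10` unless set explicitly.
#'
#' @param path Path to a YAML document; an empty document yields the default
#'   configuration.
#' @return An `htncea_config` list.
#' @export
load_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("config parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key/value mapping")
  p <- unclass(default_parameters())
  known <- c(names(p), .config_extra_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  rr_set <- "rr_intervention" %in% names(raw)
  for (nm in intersect(names(raw), names(p))) p[[nm]] <- raw[[nm]]
  if (!rr_set) p$rr_intervention <- rr_from_sbp_effect(p$delta_sbp, p$rr_per_10)
  class(p) <- "htncea_params"
  viol <- validate_parameters(p)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  cfg <- default_config(p)
  for (nm in intersect(names(raw), .config_extra_keys)) cfg[[nm]] <- raw[[nm]]
  if (!cfg$scenario %in% c("pessimistic", "intermediate", "optimistic"))
    stop("scenario: must be pessimistic, intermediate or optimistic")
  if (cfg$psa_iterations < 1) stop("psa_iterations: must be >= 1")
  if (!length(cfg$wtp_grid) || any(cfg$wtp_grid < 0))
    stop("wtp_grid: must be nonempty and nonnegative")
  cfg
}

#' Write an analysis configuration to a YAML file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg An `htncea_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  flat <- unclass(cfg$params)
  flat$scenario <- cfg$scenario
  flat$psa_iterations <- cfg$psa_iterations
  flat$seed <- cfg$seed
  flat$wtp_grid <- cfg$wtp_grid
  flat$life_table_path <- cfg$life_table_path
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}
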