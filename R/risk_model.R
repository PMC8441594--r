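#' Sex-specific coefficients of the general-CVD 10-year risk equation
#'
#' Loads the published sex-specific Cox regression coefficients of the
#' office-based general cardiovascular disease risk profile (the composite
#' 10-year CVD endpoint: coronary disease, stroke, peripheral artery disease
#' and heart failure), together with each sex's 10-year baseline survival and
#' mean linear predictor. Shipped as a plain CSV (`sex,term,value`) under
#' `extdata` so the values are auditable and replaceable.
#'
#' @param path CSV path; defaults to the bundled file.
#' @return A list with elements `male` and `female`, each a named numeric
#'   vector of terms.
#' @export
framingham_coefficients <- function(path = system.file(
    "extdata", "framingham_general_cvd.csv", package = "htncea")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "term", "value") %in% names(tab)))
  out <- lapply(split(tab, tab$sex), function(d) {
    v <- stats::setNames(d$value, d$term)
    if (any(!is.finite(v))) stop("non-finite Framingham coefficient")
    v
  })
  need <- c("ln_age", "ln_total_chol", "ln_hdl_chol", "ln_sbp_untreated",
            "ln_sbp_treated", "smoker", "diabetic",
            "baseline_survival_10y", "mean_linear_predictor")
  for (s in c("male", "female")) {
    if (is.null(out[[s]])) stop("coefficients missing for sex: ", s)
    if (!all(need %in% names(out[[s]])))
      stop("incomplete coefficient set for sex: ", s)
  }
  out[c("male", "female")]
}

#' Framingham 10-year general-CVD risk
#'
#' Computes 1 - S0^exp(L - Lbar) where L is the linear predictor in
#' log-transformed age, total and HDL cholesterol and systolic blood
#' pressure (with separate SBP coefficients for treated and untreated
#' hypertension) plus smoking and diabetes indicators. Vectorised over the
#' rows of `profiles`. Covariates outside the equation's validated ranges
#' (age 30-74, SBP 90-200, cholesterol 100-405, HDL 10-100) trigger a
#' warning but the extrapolated risk is still returned.
#'
#' @param profiles data.frame with columns `age` (years), `sex` ("male" or
#'   "female"), `sbp` (mm Hg), `total_chol`, `hdl_chol` (mg/dL), `smoker`,
#'   `diabetic`, `treated_htn` (logical).
#' @param coeffs As from [framingham_coefficients()].
#' @return Numeric vector of 10-year risks in (0, 1).
#' @export
framingham_10y_risk <- function(profiles, coeffs = framingham_coefficients()) {
  stopifnot(all(c("age", "sex", "sbp", "total_chol", "hdl_chol", "smoker",
                  "diabetic", "treated_htn") %in% names(profiles)))
  if (any(profiles$age < 30 | profiles$age > 74) ||
      any(profiles$sbp < 90 | profiles$sbp > 200) ||
      any(profiles$total_chol < 100 | profiles$total_chol > 405) ||
      any(profiles$hdl_chol < 10 | profiles$hdl_chol > 100))
    warning("covariates outside the risk equation's validated ranges; ",
            "the equation is being extrapolated")
  risk <- numeric(nrow(profiles))
  for (s in c("male", "female")) {
    i <- profiles$sex == s
    if (!any(i)) next
    b <- coeffs[[s]]
    d <- profiles[i, , drop = FALSE]
    b_sbp <- ifelse(d$treated_htn, b["ln_sbp_treated"], b["ln_sbp_untreated"])
    lp <- b["ln_age"] * log(d$age) +
      b["ln_total_chol"] * log(d$total_chol) +
      b["ln_hdl_chol"] * log(d$hdl_chol) +
      b_sbp * log(d$sbp) +
      b["smoker"] * as.numeric(d$smoker) +
      b["diabetic"] * as.numeric(d$diabetic)
    risk[i] <- 1 - b["baseline_survival_10y"] ^
      exp(lp - b["mean_linear_predictor"])
  }
  unname(risk)
}

#' Convert an event probability between time horizons
#'
#' Constant-hazard (exponential) conversion: a probability `p` over `t_from`
#' years becomes `1 - (1 - p)^(t_to / t_from)` over `t_to` years. Used to
#' turn 10-year Framingham risks into 6-month cycle probabilities.
#'
#' @param p Probability over `t_from` years, in \[0, 1\].
#' @param t_from,t_to Periods in years, both > 0.
#' @return Probability over `t_to` years.
#' @export
#' @examples
#' convert_risk_period(0.20, 10, 0.5)  # 0.011095...
convert_risk_period <- function(p, t_from, t_to) {
  if (any(t_from <= 0) || any(t_to <= 0)) stop("periods must be > 0")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  1 - (1 - p)^(t_to / t_from)
}

#' Stratify a cohort by 10-year CVD risk
#'
#' Counts individuals at or above the cutoff as high risk (ties at the
#' cutoff are high risk).
#'
#' @param risks Nonempty numeric vector of 10-year risks.
#' @param cutoff Risk cutoff (default 0.20).
#' @return List with `n_total`, `n_high`, `prop_high`, `risks`.
#' @export
stratify_cohort <- function(risks, cutoff = 0.20) {
  if (!length(risks)) stop("risks must be nonempty")
  n_high <- sum(risks >= cutoff)
  list(n_total = length(risks), n_high = n_high,
       prop_high = n_high / length(risks), risks = risks)
}

#' Relative risk of CVD events implied by an SBP change
#'
#' Maps a net systolic blood-pressure change onto a relative risk using the
#' meta-analytic RR of 0.80 per 10 mm Hg SBP reduction:
#' `exp(log(rr_per_10) / 10 * |delta_sbp|)`. The absolute value makes the
#' sign convention (negative = reduction) unable to invert the effect; a
#' zero change gives RR 1.
#'
#' @param delta_sbp Net SBP change in mm Hg (negative = reduction).
#' @param rr_per_10 RR per 10 mm Hg reduction, in (0, 1].
#' @return Relative risk in (0, 1].
#' @export
#' @examples
#' rr_from_sbp_effect(-5.3, 0.80)  # 0.8886, conventionally quoted as 0.88
rr_from_sbp_effect <- function(delta_sbp, rr_per_10) {
  if (any(rr_per_10 <= 0)) stop("rr_per_10 must be > 0")
  exp(log(rr_per_10) / 10 * abs(delta_sbp))
}

#' Per-cycle relative-risk schedule for the intervention arm
#'
#' Builds the vector of RR multipliers applied to the intervention arm's
#' event probabilities under the three extrapolation scenarios:
#' `pessimistic` confines the effect to the 18-month trial period (cycles
#' 1-3), `intermediate` (the base case) holds it for the 5-year window
#' (cycles 1-10), and `optimistic` extends it over the whole horizon.
#' Outside the effect window the multiplier is 1.
#'
#' @param scenario One of "pessimistic", "intermediate", "optimistic".
#' @param n_cycles Number of 6-month cycles (>= 1).
#' @param rr Relative risk inside the effect window, in (0, 1].
#' @return Numeric vector of length `n_cycles`.
#' @export
build_effect_schedule <- function(scenario, n_cycles, rr) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (rr <= 0 || rr > 1) stop("rr must be in (0, 1]")
  window <- switch(scenario,
                   pessimistic = 3L,
                   intermediate = 10L,
                   optimistic = n_cycles,
                   stop("unknown scenario: ", scenario))
  sched <- rep(1, n_cycles)
  sched[seq_len(min(window, n_cycles))] <- rr
  sched
}
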