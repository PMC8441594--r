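#' Fit a sampling distribution to a parameter's base value and range
#'
#' Method-of-moments fits treating (low, high) as a 95% interval, so
#' `sd = (high - low) / (2 * 1.96)`:
#' * gamma: `shape = (base/sd)^2`, `scale = sd^2/base`;
#' * beta: `alpha + beta = base(1-base)/sd^2 - 1`, `alpha = base(alpha+beta)`;
#' * lognormal: `mu = log(base)`, `sigma = (log(high) - log(low))/(2*1.96)`;
#' * triangular: (min = low, mode = base, max = high) directly.
#'
#' A beta-distributed decrement with negative base (the CVD event
#' disutility) is fitted on its magnitude and flagged `negate`, so draws are
#' returned negative. Published ranges stated as +/-25% of base are fitted
#' by the same rule as true 95% CIs.
#'
#' @param spec One row of [parameter_specs()] (name, base, low, high, dist).
#' @return List of class `dist_spec`: `name`, `family`, `pars` (named),
#'   `negate`, plus the source `base`, `low`, `high`.
#' @export
fit_distribution <- function(spec) {
  stopifnot(nrow(spec) == 1)
  family <- spec$dist
  if (family == "none") stop("parameter '", spec$name,
                             "' has no sampling distribution")
  base <- spec$base; low <- spec$low; high <- spec$high
  if (low >= high) stop("need low < high to fit a distribution")
  negate <- FALSE
  if (family == "beta" && base < 0) {
    negate <- TRUE
    tmp <- base; base <- -base
    lo <- -high; high <- -low; low <- lo
  }
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  pars <- switch(family,
    gamma = {
      if (base <= 0) stop("gamma needs base > 0")
      c(shape = (base / sd)^2, scale = sd^2 / base)
    },
    beta = {
      if (base <= 0 || base >= 1) stop("beta needs base in (0, 1)")
      ab <- base * (1 - base) / sd^2 - 1
      if (ab <= 0) stop("range too wide for a beta fit at this base")
      c(alpha = base * ab, beta = (1 - base) * ab)
    },
    lognormal = {
      if (low <= 0) stop("lognormal needs positive bounds")
      c(mu = log(base), sigma = (log(high) - log(low)) /
          (2 * stats::qnorm(0.975)))
    },
    triangular = c(min = low, mode = base, max = high),
    stop("unknown family: ", family))
  structure(list(name = spec$name, family = family, pars = pars,
                 negate = negate, base = spec$base, low = spec$low,
                 high = spec$high),
            class = "dist_spec")
}

#' Draw from a fitted parameter distribution
#'
#' @param d A `dist_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` (negated for decrement fits).
#' @export
draw_distribution <- function(d, n) {
  x <- switch(d$family,
    gamma = stats::rgamma(n, shape = d$pars["shape"], scale = d$pars["scale"]),
    beta = stats::rbeta(n, d$pars["alpha"], d$pars["beta"]),
    lognormal = stats::rlnorm(n, d$pars["mu"], d$pars["sigma"]),
    triangular = {
      # inverse-CDF triangular draw
      a <- d$pars["min"]; c_ <- d$pars["mode"]; b <- d$pars["max"]
      u <- stats::runif(n)
      fc <- (c_ - a) / (b - a)
      ifelse(u < fc, a + sqrt(u * (b - a) * (c_ - a)),
             b - sqrt((1 - u) * (b - a) * (b - c_)))
    })
  unname(if (d$negate) -x else x)
}

#' Analytic mean of a fitted distribution
#'
#' @param d A `dist_spec`.
#' @return The distribution's mean (negated for decrement fits).
#' @export
distribution_mean <- function(d) {
  m <- switch(d$family,
    gamma = d$pars["shape"] * d$pars["scale"],
    beta = d$pars["alpha"] / (d$pars["alpha"] + d$pars["beta"]),
    lognormal = exp(d$pars["mu"] + d$pars["sigma"]^2 / 2),
    triangular = (d$pars["min"] + d$pars["mode"] + d$pars["max"]) / 3)
  unname(if (d$negate) -m else m)
}

# hard admissibility bounds per parameter, used for PSA redraws
.hard_bounds <- function(name) {
  switch(name,
    p_event_high = , p_event_low = , p_cvd_fatal = , prop_high = c(0, 1),
    u_high = , u_low = c(0, 1),
    du_event = c(-1, 0),
    rr_intervention = c(1e-12, 1),
    c(0, Inf))
}

.base_icer <- function(params, lt, followup) {
  cfg <- default_config(params)
  r <- run_scenario(cfg, "intermediate", lt, followup)
  cmp <- r$comparison
  if (abs(cmp$delta_qaly) < 1e-12) return(NA_real_)
  cmp$delta_cost / cmp$delta_qaly
}

# set one parameter on a params list, keeping derived fields consistent
.set_param <- function(p, name, value) {
  p[[name]] <- value
  p
}

#' One-way (tornado) sensitivity analysis
#'
#' For every parameter flagged `in_oneway`, recomputes the base-scenario
#' (intermediate) ICER with that parameter at its low and at its high bound,
#' all others held at base. The ratio `delta_cost / delta_qaly` is reported
#' whatever the quadrant (a dominant draw yields a negative ratio), so the
#' tornado spread is always defined; an effect difference below 1e-12
#' yields NA. Entries are sorted by spread, largest first.
#'
#' @param config An `htncea_config`.
#' @param lt Life table.
#' @param followup See [accumulate_outcomes()].
#' @return data.frame with columns `parameter`, `low`, `high`, `icer_base`,
#'   `icer_at_low`, `icer_at_high`, `spread`, sorted by `spread` descending.
#' @export
one_way_sensitivity <- function(config, lt,
                                followup = c("first_year", "lifelong")) {
  followup <- match.arg(followup)
  specs <- config$specs[config$specs$in_oneway, , drop = FALSE]
  base_icer <- .base_icer(config$params, lt, followup)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    at <- vapply(c(s$low, s$high), function(v) {
      .base_icer(.set_param(config$params, s$name, v), lt, followup)
    }, numeric(1))
    data.frame(parameter = s$name, low = s$low, high = s$high,
               icer_base = base_icer, icer_at_low = at[1],
               icer_at_high = at[2],
               spread = abs(at[2] - at[1]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' Draws every `in_psa` parameter independently from its fitted
#' distribution (the discount rate, start age, horizon and mortality
#' multiplier are held fixed; the QALY trial difference and the SBP effect
#' carry no distribution; the relative risk is drawn directly from its
#' lognormal rather than re-derived from a sampled SBP effect), reruns both
#' arms of the chosen scenario per iteration, and records the incremental
#' cost and effect pair. Draws outside a parameter's hard bounds
#' (probabilities and utilities in \[0, 1\], RR in (0, 1\], costs
#' nonnegative) are redrawn; the count is reported. Identical seeds give
#' identical draw lists.
#'
#' @param config An `htncea_config`.
#' @param lt Life table.
#' @param n_iter Number of iterations (default from config).
#' @param seed Integer seed (default from config).
#' @param scenario Scenario sampled (default intermediate = base case).
#' @param followup See [accumulate_outcomes()].
#' @return List of class `psa_result`: `iterations`, `seed`, `draws`
#'   (data.frame `iteration`, `delta_cost`, `delta_qaly`), `redraws`
#'   (total redraw count), `param_draws` (matrix of sampled parameter
#'   values, one column per parameter).
#' @export
run_psa <- function(config, lt, n_iter = config$psa_iterations,
                    seed = config$seed, scenario = "intermediate",
                    followup = c("first_year", "lifelong")) {
  followup <- match.arg(followup)
  stopifnot(n_iter >= 1)
  specs <- config$specs[config$specs$in_psa, , drop = FALSE]
  dists <- lapply(seq_len(nrow(specs)),
                  function(i) fit_distribution(specs[i, ]))
  names(dists) <- specs$name
  old <- .Random.seed_exists()
  set.seed(seed)
  redraws <- 0L
  draws_mat <- vapply(dists, function(d) {
    x <- draw_distribution(d, n_iter)
    b <- .hard_bounds(d$name)
    bad <- which(x < b[1] | x > b[2])
    guard <- 0L
    while (length(bad)) {
      redraws <<- redraws + length(bad)
      x[bad] <- draw_distribution(d, length(bad))
      bad <- bad[x[bad] < b[1] | x[bad] > b[2]]
      guard <- guard + 1L
      if (guard > 1000L) stop("redraw limit hit for ", d$name)
    }
    x
  }, numeric(n_iter))
  if (n_iter == 1L) draws_mat <- matrix(draws_mat, nrow = 1,
                                        dimnames = list(NULL, names(dists)))
  .restore_seed(old)
  dc <- de <- numeric(n_iter)
  n_cyc <- .n_cycles(config$params)
  for (it in seq_len(n_iter)) {
    p <- config$params
    for (nm in colnames(draws_mat)) p[[nm]] <- unname(draws_mat[it, nm])
    sched <- build_effect_schedule(scenario, n_cyc, p$rr_intervention)
    ctrl <- run_arm("control", p, sched, lt, followup)
    intv <- run_arm("intervention", p, sched, lt, followup)
    dc[it] <- intv$discounted_cost - ctrl$discounted_cost
    de[it] <- intv$discounted_qaly - ctrl$discounted_qaly
  }
  structure(list(iterations = n_iter, seed = seed,
                 draws = data.frame(iteration = seq_len(n_iter),
                                    delta_cost = dc, delta_qaly = de),
                 redraws = redraws, param_draws = draws_mat),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws whose net
#' monetary benefit `wtp * delta_qaly - delta_cost` is positive.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Nonempty vector of WTP values (INT$/QALY).
#' @return data.frame with columns `wtp`, `probability_cost_effective`.
#' @export
compute_ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) stop("wtp_grid must be nonempty")
  if (!nrow(psa$draws)) stop("psa has no draws")
  pr <- vapply(wtp_grid, function(w)
    mean(net_monetary_benefit(psa$draws$delta_cost,
                              psa$draws$delta_qaly, w) > 0),
    numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = pr)
}
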