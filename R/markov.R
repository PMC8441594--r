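#' @keywords internal
"_PACKAGE"

# Internal state layout. The published model has 3 states (low risk, high
# risk, death); the one-year post-event cost and disutility require knowing
# time since event, so the high-risk state is refined into two 6-month
# tunnel sub-states plus a post-event chronic state. `high` holds members
# who started high risk and never had an event; `high_pe` holds event
# survivors who completed the tunnel (kept separate only so that the
# optional lifelong follow-up cost can find them). All four aggregate to
# the published high-risk state.
.states <- c("low", "high", "tun1", "tun2", "high_pe", "dead")
.living <- .states[1:5]
.high_agg <- c("high", "tun1", "tun2", "high_pe")

#' Six-month background mortality from a life table
#'
#' Converts the annual death probability at `floor(age)`, scaled by
#' `multiplier` and capped at 1, to a cycle-length probability under a
#' constant within-year hazard. Ages beyond the table's terminal age return
#' 1 (death is certain past the assumed maximum lifespan); ages below the
#' table's first age are an error.
#'
#' @param lt A `life_table`.
#' @param age Age in years (may be non-integer).
#' @param multiplier Positive scaling of the annual probability.
#' @param cycle_years Cycle length in years.
#' @return Probability of death within one cycle.
#' @export
cycle_mortality <- function(lt, age, multiplier = 1, cycle_years = 0.5) {
  if (multiplier <= 0) stop("multiplier must be > 0")
  a <- floor(age)
  if (any(a < min(lt$age))) stop("age below life-table range")
  qx <- ifelse(a > max(lt$age), 1, lt$qx[match(pmin(a, max(lt$age)), lt$age)])
  q <- pmin(qx * multiplier, 1)
  1 - (1 - q)^cycle_years
}

# Per-cycle event probability by living state for one arm.
.event_probs <- function(p, rr_mult) {
  c(low = p$p_event_low * rr_mult,
    high = p$p_event_high * rr_mult,
    tun1 = p$p_event_high * rr_mult,
    tun2 = p$p_event_high * rr_mult,
    high_pe = p$p_event_high * rr_mult)
}

#' One cycle's transition matrix
#'
#' Transition probabilities for each state over one cycle, given the arm's
#' effect-schedule multiplier for that cycle. Within a cycle, background
#' mortality acts first; survivors face the state's CVD event probability
#' (low-risk states use the low-risk probability, all high-risk aggregate
#' states the high-risk one) scaled by the schedule multiplier; a fraction
#' `p_cvd_fatal` of events is fatal and survivors enter the first tunnel
#' state. Event-free survivors progress tunnel 1 -> tunnel 2 -> post-event
#' chronic high risk; the low and chronic high states are otherwise
#' absorbing among the living.
#'
#' @param p Model parameters.
#' @param arm "control" or "intervention".
#' @param cycle_index 1-based cycle number.
#' @param schedule RR multipliers per cycle (see [build_effect_schedule()]);
#'   ignored for the control arm.
#' @param lt Life table.
#' @param age Cohort age at the start of the cycle.
#' @return 6x6 row-stochastic matrix over states
#'   low/high/tun1/tun2/high_pe/dead.
#' @export
build_cycle_transitions <- function(p, arm, cycle_index, schedule, lt,
                                    age = p$start_age +
                                      (cycle_index - 1) * p$cycle_years) {
  arm <- match.arg(arm, c("control", "intervention"))
  rr_mult <- if (arm == "intervention") schedule[cycle_index] else 1
  q <- cycle_mortality(lt, age, p$mortality_multiplier, p$cycle_years)
  pe <- .event_probs(p, rr_mult)
  if (any(pe > 1) || q > 1)
    stop("transition probabilities exceed 1; check parameters")
  M <- matrix(0, 6, 6, dimnames = list(.states, .states))
  dest_no_event <- c(low = "low", high = "high", tun1 = "tun2",
                     tun2 = "high_pe", high_pe = "high_pe")
  for (s in .living) {
    M[s, "dead"] <- q + (1 - q) * pe[s] * p$p_cvd_fatal
    M[s, "tun1"] <- M[s, "tun1"] + (1 - q) * pe[s] * (1 - p$p_cvd_fatal)
    d <- dest_no_event[s]
    M[s, d] <- M[s, d] + (1 - q) * (1 - pe[s])
  }
  M["dead", "dead"] <- 1
  stopifnot(all(abs(rowSums(M) - 1) < 1e-12))
  M
}

#' Run the deterministic cohort simulation for one arm
#'
#' Propagates state occupancy fractions from the initial distribution
#' (`1 - prop_high` low risk, `prop_high` high risk) through
#' `length(schedule)` cycles, advancing age by one cycle length per cycle.
#'
#' @inheritParams build_cycle_transitions
#' @param schedule Effect schedule; its length sets the number of cycles.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   ((n_cycles + 1) x 6 matrix, cycle-start occupancy plus final), `events`,
#'   `event_deaths`, `background_deaths` (per-cycle fractions of the initial
#'   cohort), `ages`, `arm`.
#' @export
run_cohort <- function(arm, p, schedule, lt) {
  arm <- match.arg(arm, c("control", "intervention"))
  n <- length(schedule)
  occ <- matrix(0, n + 1, 6, dimnames = list(NULL, .states))
  occ[1, ] <- c(1 - p$prop_high, p$prop_high, 0, 0, 0, 0)
  events <- event_deaths <- bg_deaths <- numeric(n)
  ages <- p$start_age + (seq_len(n) - 1) * p$cycle_years
  for (k in seq_len(n)) {
    M <- build_cycle_transitions(p, arm, k, schedule, lt, ages[k])
    x <- occ[k, ]
    occ[k + 1, ] <- as.numeric(x %*% M)
    q <- cycle_mortality(lt, ages[k], p$mortality_multiplier, p$cycle_years)
    rr_mult <- if (arm == "intervention") schedule[k] else 1
    pe <- .event_probs(p, rr_mult)
    alive <- x[.living]
    events[k] <- sum(alive * (1 - q) * pe)
    event_deaths[k] <- events[k] * p$p_cvd_fatal
    bg_deaths[k] <- sum(alive) * q
  }
  structure(list(occupancy = occ, events = events,
                 event_deaths = event_deaths, background_deaths = bg_deaths,
                 ages = ages, arm = arm),
            class = "cohort_trace")
}

#' Discounted, half-cycle-corrected costs and QALYs for a trace
#'
#' Applies the accounting rules to a cohort trace. State-membership
#' quantities (health-service and programme costs, follow-up costs, state
#' utilities and the event disutility) use trapezoid half-cycle-corrected
#' occupancy, the mean of cycle-start and cycle-end occupancy; event costs
#' attach to event incidence (fatal and non-fatal alike) and are not
#' half-cycle diluted. Everything is discounted at the cycle midpoint,
#' `(1 + r)^-((k - 0.5) * cycle_years)`.
#'
#' Cost components: the arm's per-cycle health-service cost for every living
#' member; the programme cost (intervention arm, trial cycles 1-3 only); the
#' per-event acute cost; and the annual post-event follow-up cost, charged
#' during the one-year tunnel (default) or, with `followup = "lifelong"`,
#' for the rest of every event survivor's life. QALY components: state
#' utilities (tunnel states carry the high-risk utility), the first-year
#' event disutility on tunnel occupancy, and the trial QALY difference
#' added to the intervention arm in equal thirds over cycles 1-3, scaled by
#' the living fraction.
#'
#' @param trace A `cohort_trace`.
#' @param p Model parameters.
#' @param arm "control" or "intervention"; defaults to the trace's arm.
#' @param followup Charge the CVD follow-up cost during the first post-event
#'   year only (default) or lifelong.
#' @return Object of class `arm_result`: list with `discounted_cost`,
#'   `discounted_qaly`, `total_events` (expected events per person,
#'   undiscounted), `life_years` (undiscounted).
#' @export
accumulate_outcomes <- function(trace, p, arm = trace$arm,
                                followup = c("first_year", "lifelong")) {
  followup <- match.arg(followup)
  arm <- match.arg(arm, c("control", "intervention"))
  occ <- trace$occupancy
  n <- length(trace$events)
  k <- seq_len(n)
  nbar <- (occ[k, , drop = FALSE] + occ[k + 1, , drop = FALSE]) / 2
  disc <- (1 + p$discount_rate)^(-(k - 0.5) * p$cycle_years)
  alive <- rowSums(nbar[, .living, drop = FALSE])
  tunnel <- nbar[, "tun1"] + nbar[, "tun2"]
  fu_occ <- if (followup == "lifelong") tunnel + nbar[, "high_pe"] else tunnel
  c_hs <- if (arm == "intervention") p$c_hs_intervention else p$c_hs_control
  cost_k <- c_hs * alive +
    p$c_event * trace$events +
    p$c_event_followup * p$cycle_years * fu_occ
  if (arm == "intervention")
    cost_k <- cost_k + p$c_program * alive * (k <= 3)
  high_occ <- rowSums(nbar[, .high_agg, drop = FALSE])
  qaly_k <- p$cycle_years * (p$u_low * nbar[, "low"] +
                             p$u_high * high_occ +
                             p$du_event * tunnel)
  if (arm == "intervention")
    qaly_k <- qaly_k + (p$qaly_diff_trial / 3) * alive * (k <= 3)
  structure(list(discounted_cost = sum(disc * cost_k),
                 discounted_qaly = sum(disc * qaly_k),
                 total_events = sum(trace$events),
                 life_years = sum(p$cycle_years * alive)),
            class = "arm_result")
}

#' Run one arm end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate_outcomes()].
#'
#' @inheritParams accumulate_outcomes
#' @inheritParams run_cohort
#' @return An `arm_result`.
#' @export
run_arm <- function(arm, p, schedule, lt,
                    followup = c("first_year", "lifelong")) {
  accumulate_outcomes(run_cohort(arm, p, schedule, lt), p, arm, followup)
}

#' Patient-level microsimulation oracle
#'
#' Simulates individual trajectories through exactly the per-cycle
#' probabilities and accounting rules of the cohort model, by random draws.
#' Exists as an independent cross-check of the deterministic engine: cohort
#' results must lie within Monte Carlo error of the microsimulation means.
#' The initial low/high split is deterministic (`round(n * prop_high)`
#' patients start high risk) so the oracle estimates the same initial
#' distribution the cohort model uses.
#'
#' @inheritParams run_arm
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; runs are reproducible.
#' @return List with `discounted_cost`, `discounted_qaly`, `total_events`,
#'   `life_years` (means per patient), and `se_cost`, `se_qaly` (Monte Carlo
#'   standard errors of the two means).
#' @export
microsim_oracle <- function(arm, p, schedule, lt, n_patients = 10000,
                            seed = 1L,
                            followup = c("first_year", "lifelong")) {
  followup <- match.arg(followup)
  arm <- match.arg(arm, c("control", "intervention"))
  stopifnot(n_patients >= 1)
  old <- .Random.seed_exists()
  set.seed(seed)
  n_cyc <- length(schedule)
  S <- stats::setNames(seq_along(.states), .states)
  n_high0 <- round(n_patients * p$prop_high)
  state <- c(rep(S["high"], n_high0), rep(S["low"], n_patients - n_high0))
  cost <- qaly <- events_i <- ly <- numeric(n_patients)
  c_hs <- if (arm == "intervention") p$c_hs_intervention else p$c_hs_control
  dest_no_event <- unname(S[c("low", "high", "tun2", "high_pe", "high_pe",
                              "dead")])  # indexed by current state
  for (k in seq_len(n_cyc)) {
    age <- p$start_age + (k - 1) * p$cycle_years
    q <- cycle_mortality(lt, age, p$mortality_multiplier, p$cycle_years)
    rr_mult <- if (arm == "intervention") schedule[k] else 1
    pe_by_state <- c(p$p_event_low, p$p_event_high, p$p_event_high,
                     p$p_event_high, p$p_event_high, 0) * rr_mult
    alive0 <- state != S["dead"]
    new_state <- state
    die_bg <- alive0 & (stats::runif(n_patients) < q)
    new_state[die_bg] <- S["dead"]
    at_risk <- alive0 & !die_bg
    ev <- at_risk & (stats::runif(n_patients) < pe_by_state[state])
    fatal <- ev & (stats::runif(n_patients) < p$p_cvd_fatal)
    new_state[ev & !fatal] <- S["tun1"]
    new_state[fatal] <- S["dead"]
    prog <- at_risk & !ev
    new_state[prog] <- dest_no_event[state[prog]]
    # accounting, identical rules to accumulate_outcomes
    nbar <- function(s) ((state == S[s]) + (new_state == S[s])) / 2
    alive_bar <- (alive0 + (new_state != S["dead"])) / 2
    tun_bar <- nbar("tun1") + nbar("tun2")
    fu_bar <- if (followup == "lifelong") tun_bar + nbar("high_pe") else tun_bar
    high_bar <- nbar("high") + nbar("tun1") + nbar("tun2") + nbar("high_pe")
    disc <- (1 + p$discount_rate)^(-(k - 0.5) * p$cycle_years)
    ck <- c_hs * alive_bar + p$c_event * ev +
      p$c_event_followup * p$cycle_years * fu_bar
    if (arm == "intervention" && k <= 3)
      ck <- ck + p$c_program * alive_bar
    qk <- p$cycle_years * (p$u_low * nbar("low") + p$u_high * high_bar +
                           p$du_event * tun_bar)
    if (arm == "intervention" && k <= 3)
      qk <- qk + (p$qaly_diff_trial / 3) * alive_bar
    cost <- cost + disc * ck
    qaly <- qaly + disc * qk
    events_i <- events_i + ev
    ly <- ly + p$cycle_years * alive_bar
    state <- new_state
  }
  .restore_seed(old)
  list(discounted_cost = mean(cost), discounted_qaly = mean(qaly),
       total_events = mean(events_i), life_years = mean(ly),
       se_cost = stats::sd(cost) / sqrt(n_patients),
       se_qaly = stats::sd(qaly) / sqrt(n_patients))
}

#' Export a cohort trace as a per-cycle table
#'
#' One row per cycle: age, occupancy at cycle start (post-event states
#' aggregated into the published high-risk state), new events and deaths.
#'
#' @param trace A `cohort_trace`.
#' @return data.frame with columns `cycle`, `age`, `low`, `high`, `dead`,
#'   `new_events`, `event_deaths`, `background_deaths`.
#' @export
trace_table <- function(trace) {
  n <- length(trace$events)
  occ <- trace$occupancy[seq_len(n), , drop = FALSE]
  data.frame(cycle = seq_len(n), age = trace$ages,
             low = occ[, "low"],
             high = rowSums(occ[, .high_agg, drop = FALSE]),
             dead = occ[, "dead"],
             new_events = trace$events,
             event_deaths = trace$event_deaths,
             background_deaths = trace$background_deaths)
}

# save/restore the RNG state so seeded helpers do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
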