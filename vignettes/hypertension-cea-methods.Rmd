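---
title: "Methods: lifetime cost-effectiveness of multicomponent hypertension control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime cost-effectiveness of multicomponent hypertension control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The decision problem

An 18-month cluster-randomised trial in low-income Argentine public primary
care showed that a community-health-worker-led multicomponent programme
(home coaching, home blood-pressure monitoring, physician training, text
messaging) lowers systolic blood pressure by a net 5.3 mm Hg relative to
usual care. `htncea` extrapolates that short-term effect over a lifetime: it
asks whether the programme's extra costs (the programme itself plus higher
health-service utilization) are justified by the cardiovascular events it
prevents, measured as an incremental cost per quality-adjusted life-year
(QALY) against a willingness-to-pay threshold of INT$18 000/QALY (Argentine
GDP per head, 2017, in purchasing-power-parity international dollars at
11.47 ARS/INT$).

# Model structure

The core is a Markov cohort state-transition model with a 6-month cycle, a
45-year horizon (90 cycles) from a starting age of 55, and three published
health states: *low CVD risk*, *high CVD risk* and *death*. Patients are
assigned to the initial risk states by their Framingham 10-year general-CVD
risk (composite endpoint) with a 20% cutoff; ties at the cutoff count as
high risk (the boundary is a documented convention — the source does not
specify it). The base case starts 60% of the cohort in the high-risk state.

Each cycle, living patients face:

1. **Background mortality** from an age-specific all-sex life table,
   converted from an annual to a 6-month probability by the constant-hazard
   rule $1-(1-q_x)^{1/2}$ and read at `floor(age)`. The terminal table age
   (100) carries $q_x = 1$, so life ends at 100 at the latest; modelled ages
   beyond the table are treated as certain death, which is what lets the
   one-way analysis push the starting age to 70 or the horizon to 56.5
   years without an inconsistent age/horizon combination.
2. **A CVD event** with 6-month probability 0.0058 (low risk) or 0.0267
   (high risk). A fraction 0.30 of events is fatal; survivors enter the
   high-risk pool.

The ordering within a cycle — mortality first, then events among survivors,
then case fatality — is a fixed convention; the patient-level
microsimulation oracle uses the identical ordering so the two engines are
comparable draw for draw.

## The one-year post-event tunnel

The published model charges an event-related utility decrement (−0.2775)
and a follow-up cost (INT$300/year) "within 1 year" of an event, yet
describes only three states. The only structure that honours both is a
tunnel: event survivors pass through two consecutive 6-month tunnel
sub-states that aggregate to the published high-risk state for reporting.
Internally the engine therefore tracks
`low / high / tunnel-1 / tunnel-2 / post-event-chronic / dead`; the
post-event-chronic split exists solely so the optional lifelong follow-up
cost switch can find event survivors. Whether follow-up costs stop after
the first year or continue for life is not stated in the source; both are
implemented (`followup = "first_year"` is the default) and the choice moves
results by well under the uncertainty ranges.

## Treatment effect and scenarios

The trial's net SBP effect maps to a relative risk of CVD events via
$RR = \exp(\ln(0.80)/10 \times |\Delta SBP|)$, the meta-analytic 0.80 per
10 mm Hg reduction: $\Delta SBP = -5.3$ gives $RR = 0.8886$, conventionally
quoted as 0.88. The model stores the derived value at full precision; the
sensitivity-analysis specification row carries the quoted 0.88 with its
published interval (0.79–0.99, stored low-to-high), so the fitted lognormal
matches the published parameterisation. This is the one place where the
deterministic engine and the uncertainty machinery use slightly different
base values (0.8886 vs 0.88) — a deliberate trade-off, documented here,
favouring each component's own published definition.

Because randomisation balanced baseline risk, the Table-2 event
probabilities are treated as the common (control) baseline and the
intervention arm multiplies them by the RR during the scenario's effect
window — applying the RR on top of intervention-specific probabilities
would double count the effect.

Three scenarios extrapolate the effect: *pessimistic* (RR applies during
the 18-month trial only, cycles 1–3), *intermediate* — the base case — (a
5-year window, cycles 1–10) and *optimistic* (lifelong). The windows map
exactly onto whole 6-month cycles.

## Accounting

Costs and QALYs accrue per cycle with trapezoid half-cycle correction
(state membership averaged between cycle start and end) and midpoint
discounting at 5%/year, $(1+r)^{-(k-0.5)/2}$:

* health-service cost per living member: INT$82.69/cycle (control) or
  INT$105.30/cycle (intervention, all cycles — back-calculation against
  the published incremental costs shows the 22.61 INT$/cycle utilization
  difference must persist lifelong, not just during the trial);
* programme cost INT$53.88/cycle, intervention arm, cycles 1–3 only;
* event cost INT$1732.47 per event (fatal or not), attached to incidence
  and *not* half-cycle diluted — events are instantaneous, the correction
  applies to state-membership quantities;
* follow-up cost INT$300/year during the tunnel;
* utilities 0.8176 (low risk) and 0.7963 (all high-risk aggregate states)
  per year, −0.2775/year extra on tunnel occupancy, and the trial-measured
  QALY difference of 0.0420 added to the intervention arm in equal thirds
  over cycles 1–3, scaled by the living fraction.

With zero discount the accumulator reduces exactly to the undiscounted
half-cycle-corrected sums (a tested identity), and a fully neutralised
intervention arm (RR 1, equal costs, no programme cost, no QALY add-on) is
bit-identical to control.

# Uncertainty analysis

**Distributions.** Each parameter's published range is treated as a 95%
interval, $sd = (high - low)/(2 \times 1.96)$, and fitted by method of
moments: gamma for costs, beta for probabilities and utilities, lognormal
for the RR, triangular (min, mode, max) for case fatality. Ranges published
as ±25% of base are fitted by the same rule — the source does not
distinguish them. The CVD event disutility is a *negative* beta-distributed
quantity: it is fitted on its magnitude and negated on draw. Fitted
beta/gamma/lognormal means sit within 1% of their base values (tested).

**One-way (tornado).** Every parameter flagged for one-way analysis —
including the discount rate, starting age, horizon and a mortality
multiplier (base 1.0, ±25%) that stands in for the unpublished life-table
range — is set to each bound with everything else at base, and the
intermediate-scenario ICER recomputed. The ratio ΔC/ΔE is reported
whatever the quadrant so the spread is always defined.

**PSA.** Second-order Monte Carlo (default 5000 iterations): all
PSA-flagged parameters are drawn independently (no correlation structure is
published), the discount rate and starting age are held fixed, and the RR
is drawn directly from its lognormal rather than re-derived from a sampled
SBP effect, because the SBP effect itself is excluded from sensitivity
analysis. Draws violating hard bounds (probabilities or utilities outside
[0, 1], RR above 1) are *redrawn*, not truncated, to keep distribution
means at their base values; redraw counts are reported (they are rare —
the only non-negligible source is the RR's upper tail, about 1% of draws).
The acceptability curve (CEAC) is the fraction of draws with positive net
monetary benefit $\lambda \Delta E - \Delta C$ at each willingness-to-pay
$\lambda$.

# Synthetic inputs

Nothing in the pipeline downloads data; two generators provide calibrated
stand-ins, and real data in the same CSV formats substitute without code
change.

**Life table.** The Argentine national life table the analysis needs is
not published with the model, so a Gompertz–Makeham table
($q_x = 1-\exp(-(a + b e^{cx}))$, $a = 5\times10^{-4}$,
$b = 2.3\times10^{-5}$, $c = 0.10$, terminal age 100) is calibrated to a
remaining life expectancy at 55 of ≈25.2 years, matching Argentine 2017
all-sex mortality. It is deliberately smooth: it has no infant-mortality
hump and no accident bump at young-adult ages, which is irrelevant here
because the cohort enters at 55.

**Trial panel.** The cohort generator draws both arms from identical
baseline distributions (age 56.2 ± 12, 46% male, and blood-pressure,
lipid, smoking, diabetes and treatment distributions chosen once so that
≈60% of baseline Framingham risks exceed the 20% cutoff — the published
calibration anchor). The panel simulator adds SBP trajectories (linear
secular drift plus a linear intervention effect reaching −5.3 mm Hg net at
month 18, noise SD 8 mm Hg), utilities at months 0 and 18 truncated to
[−0.28, 1] (the floor implied by the event disutility, the ceiling by full
health — note the ceiling biases high utility means down by up to ~0.02,
visible in recovery tests), and per-period service utilization as Poisson
counts times unit costs whose expectations reproduce the published per-arm
per-cycle service costs, with 15% follow-up missingness to exercise the
last-observation-carried-forward rule. The estimation step then recovers
the model's trial-derived inputs exactly the way the analysis describes:
LOCF imputation, per-cycle costs averaged over the three follow-up
periods, 6-month utilities by linear interpolation of the 0- and 18-month
values, the net SBP effect by difference-in-differences, and the high-risk
proportion by Framingham stratification.

What the generator does **not** emulate: cluster-level correlation (the
real trial randomised health centres, not patients), informative
missingness, utility–risk correlation, and secular treatment drift in the
control arm beyond a fixed linear term. Passing recovery tests therefore
show the estimators are consistent under the stated sampling model, not
that they are robust to those real-data features.

# Verification strategy

A patient-level microsimulation using the identical probabilities and
accounting rules serves as an independent oracle: cohort results must lie
within 3 Monte Carlo standard errors of the microsimulation mean at
50 000 patients, for both arms and all three scenarios. Other tested
invariants: occupancy conservation to 1e−12 each cycle with nondecreasing
deaths; scenario monotonicity (optimistic ≥ intermediate ≥ pessimistic
QALYs, events reversed); CEAC analytic limits at willingness-to-pay 0 and
∞; and hand-computed two-cycle worked examples for the accounting.

# Problem sizes

The package's own default scales: 90 cycles per cohort run; 5000 PSA
iterations in the analysis driver and acceptance script (1000 in the test
suite, where the binomial standard error of the acceptability probability
is already below one percentage point); 50 000 patients per
oracle-equivalence check; 2000 patients/arm for parameter-recovery tests
and 743/arm (trial scale) for the default panel.

# Known limitations

* Results with the bundled synthetic life table reproduce the *structure*
  of the published findings (ICER ordering across scenarios, everything
  far below the WTP threshold, tornado dominated by health-service costs
  and the RR) but not the published point values: those depend on the
  actual Argentine life table and on accounting conventions the source
  does not fully specify. Supplying a real `age,qx` CSV changes the
  numbers without any code change.
* Event probabilities are age-invariant apart from the scenario windows;
  all age dependence of mortality comes from the life table.
* No second-event state is modelled (a conservative simplification carried
  over from the source), no sex-stratified mortality, and no
  expected-value-of-perfect-information analysis.
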