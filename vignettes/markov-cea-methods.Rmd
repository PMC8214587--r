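---
title: "Methods: a 3-state Markov cost-effectiveness model for first-line NSCLC immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3-state Markov cost-effectiveness model for first-line NSCLC immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the design decisions
taken where the design was genuinely open.

## The decision problem

Three first-line strategies for metastatic non-squamous NSCLC with PD-L1
expression ≥ 50% are compared from a healthcare-payer perspective:
platinum–pemetrexed chemotherapy (followed on progression by second-line
pembrolizumab or best supportive care), pembrolizumab monotherapy (followed
by second-line chemotherapy or BSC), and pembrolizumab plus chemotherapy
(followed by second-line docetaxel or BSC). The evaluation horizon is 10
years of monthly cycles, with 3% annual discounting of costs and QALYs and
a CHF 100,000/QALY willingness-to-pay reference.

## Model structure

The cohort model has three mutually exclusive states: progression-free
(PFS), progressive disease (PD) and death. The cohort starts entirely in
PFS. Cycle `t` spans months `(t, t+1]`; transitions are evaluated at cycle
start.

Two fitted survivor functions per strategy drive the transitions. Each is
converted to per-cycle exit probabilities by the survivor-ratio formula
`tp_t = 1 - S(t+1)/S(t)`.

**Death allocation (a genuinely open choice).** The curves are fitted
independently, and nothing in the two marginals says how OS-derived deaths
split between PFS and PD occupants. We apply the OS exit probability
uniformly to *all* alive states and define progression as the residual of
the PFS exit: `p_pfs_to_pd(t) = max(0, pfs_exit(t) - p_death(t))`. This is
the simplest construction consistent with both curves, and it has a strong
structural consequence that the test suite asserts exactly: modelled
all-cause survival equals the fitted OS survivor at every cycle boundary,
to floating-point precision. The alternative (state-specific mortality with
a background floor in PFS) would need information the two fitted marginals
do not contain.

**Flooring.** Where the PFS exit probability falls below the death
probability, progression is floored at zero and a warning reports the
count of floored cycles. With a lognormal PFS (decreasing late hazard) and
an exponential OS (constant hazard) this routinely happens in the far tail
of the horizon, where PFS occupancy is already small; the consequence is
that modelled PFS occupancy can slightly exceed the fitted PFS survivor at
late cycles, while all-cause survival remains exact.

**Tunnel states.** PD occupancy is subdivided by tunnel age — months since
progression — so that second-line costs and utilities can depend on time in
the state without violating the Markov property. Tunnel age drives costing
and utility lookup only; it never alters transition probabilities. Since
second-line progression is modelled as a deterministic tunnel-age threshold
(4.2 months for second-line chemotherapy, 5.2 months for second-line
pembrolizumab, taken from second-line trial results), no stochastic 2L PFS
curve is needed.

**Half-cycle correction** is implemented as reward weighting on the mean of
start- and end-of-cycle occupancy, the standard cohort-model correction for
transitions occurring on average mid-cycle. Discounting uses the cycle
midpoint `(t + 0.5)/12` years when the correction is on, `t/12` otherwise.

## Survival stage

**Candidate families.** Exponential, Weibull, lognormal, log-logistic and
Gompertz — the conventional HTA screening set. The lognormal is
parameterized on natural-log time; the Gompertz with shape (any real) and
rate (> 0).

**Fitting.** Maximum likelihood under right censoring, optimized on an
unconstrained scale (log for positive parameters) with BFGS plus a
Nelder-Mead restart, analytic gradient for the exponential. The covariance
matrix comes from the numerically differentiated observed information on
the same unconstrained scale — which is exactly the scale on which PSA
draws survival parameters, so the fit's uncertainty feeds the PSA without
transformation error. The test suite cross-checks fits against
`flexsurv::flexsurvreg()` and against the exponential's closed-form MLE
(events over exposure).

**Selection.** Minimum AIC by default, BIC reported alongside; exact ties
break by fewer parameters, then by the fixed family order. "Visual
inspection of the long-term tail" is operationalized as a reported but
non-blocking statistic: `glance()` prints `S(120)` for each candidate so an
analyst can reject families with implausible 10-year tails; automated
selection remains criterion-based.

**Digitized curves.** When only published Kaplan–Meier figures are
available, `reconstruct_ipd()` rebuilds pseudo-IPD from digitized
coordinates and the numbers-at-risk table: events are allocated at
coordinate times to reproduce each survival drop given the running at-risk
count, censorings are allocated at risk-table times to reconcile the count,
and the remaining cohort is administratively censored at the end of
follow-up. Events falling between coordinates are lumped at the next
coordinate, so the reconstruction is exact *at the coordinate grid*; under
purely administrative censoring the per-interval event counts are exact
too. A weighted least-squares fit directly to coordinates was considered
as a fallback fitting mode and rejected: pseudo-IPD feeds the same MLE
path as real IPD, giving one likelihood, one AIC definition and one
covariance convention throughout.

**PH diagnostic.** `ph_diagnostic()` is the Schoenfeld-residual score test
of a log-time interaction on the two-group hazard ratio
(`survival::cox.zph(transform = "log")`). A rejected PH assumption is the
standard ground for modelling trial arms individually rather than pooling
them through a hazard-ratio comparison — the situation this package's
three-strategy setting is built for. The choice of the log-time transform
is ours; the test suite checks the nominal type-I error under the null and
the power against a hazard that halves mid-follow-up.

## Economics

Costs accrue per cycle as occupancy × unit cost × discount factor, with
fractional treatment durations (2.76-month induction, 4.2/5.2-month
second-line progression times) pro-rated within the boundary month rather
than rounded — at 1-month resolution, rounding a 2.76-month course to 3
months would systematically inflate drug costs by ~9%.

Key costing conventions, each of which the published sources leave open:

* **First line** accrues to PFS occupants while each regimen component is
  on treatment. Pemetrexed maintenance is capped at 35 cycles after the
  2.76-month induction; pembrolizumab carries its licence cap of 35
  three-weekly cycles (~2 years modelled as 35 months). The maintenance
  cap — not the licence cap — is what scenario 6 lifts.
* **Second line** accrues to PD occupants whose tunnel age is below both
  the component's duration and the second-line progression threshold,
  scaled by the second-line uptake probability; BSC costs cover the
  non-uptake share from tunnel age zero and everyone past second-line
  progression.
* **Adverse events** of first-line treatment enter as a single
  incidence-weighted one-off at model entry (grade 3–4 categories:
  pneumonitis, anaemia, colitis, exanthema/rash, other). Second-line AE
  costs are neglected, and AEs carry no disutility — they are a cost-only
  phenomenon here.
* **End of life** is a one-off applied to new deaths at the death cycle's
  discount factor. Timing at death (rather than at model entry amortized)
  was chosen because the quantity is driven by terminal-care resource use.
* **Time-on-treatment mode** (scenario 7) replaces PFS-occupancy weighting
  of first-line drug and administration costs by the strategy's ToT
  survivor curve, holding health-state occupancy — and therefore QALYs —
  unchanged. Diagnostics remain occupancy-weighted: imaging follows the
  patient, not the infusion chair.

Utilities: one PFS utility under first-line treatment; PD utilities
stratified by second-line treatment while on active 2L, BSC utility
otherwise. The generator enforces the HTA convention that the PFS utility
strictly exceeds every PD utility.

## CEA and uncertainty

ICERs are computed from unrounded values and rounded only at presentation;
dominance quadrants are mapped to flags, never to fabricated ratios. The
efficiency frontier (strict and extended dominance, strictly increasing
sequential ICERs) is provided as an additional output beyond the three
conventional pairwise comparisons.

**One-way analysis** varies each of 33 parameters between bounds (95%
intervals of the parameter's distribution; an explicit 0–5% range for the
discount rate) holding the rest central: 9 survival parameters (OS log
rate, PFS meanlog, PFS log sdlog × 3 strategies), 9 unit costs, 3
first-line AE totals, 5 utilities, the discount rate, 3 second-line uptake
probabilities and 3 second-line progression times. The published analysis
this mirrors names "33 individual parameters" without listing them; this
composition is our documented choice. Tornado legs that produce dominance
are flagged (the plot draws them at the WTP boundary with an asterisk);
legs whose configuration fails validation are recorded as failed legs.

**PSA** draws gamma for costs and durations, beta for utilities and
probabilities (the two-category second-line mix reduces the Dirichlet to a
beta), and normal on the unconstrained scale for survival parameters. OS
and PFS parameters are drawn independently: the curves are fitted to
separate endpoints and no cross-endpoint covariance is available — a known
limitation shared with the independent-curve modelling approach itself.
The default draw count is 10,000; every analysis takes a mandatory seed and
no global RNG state leaks (`with_seed` scoping).

**Scenarios 1–8**: generic pemetrexed price; cross-over-adjusted
chemotherapy OS with no second-line pembrolizumab; 0% and 5% discounting;
5-year horizon; unlimited pemetrexed maintenance; ToT costing; lognormal OS
everywhere (probing the constant-hazard assumption). The scenario engine is
stateless — it returns a modified copy and never mutates its input.

On the maintenance-cap scenario: with second-line progression fixed at 4.2
months, a 35-cycle cap on *second-line* maintenance can never bind; the
only way lifting the cap can raise costs — and raise them most for the
strategies whose first-line regimens carry pemetrexed — is if the cap binds
the *first-line* maintenance component paid during PFS. The package
therefore attaches the cap to first-line pemetrexed maintenance (and,
inertly, to the second-line component), and the scenario-6 test asserts
exactly that differential: chemotherapy and combination costs rise,
pembrolizumab monotherapy is unchanged, QALYs everywhere untouched.

## The synthetic-data generator

`generate_paramset()` emulates the *structure* of the published evaluation
— three strategies with their second-line mixes and durations, the cost
category layout, the utility stratification — with realistic but synthetic
magnitudes, because the underlying analysis keeps its unit costs and
fitted curve parameters in supplementary material. Survival defaults
(exponential OS rates 0.045/0.0265/0.0235 per month; lognormal PFS
(1.5, 1.0)/(2.3, 1.3)/(2.45, 1.3)) were chosen once to give undiscounted
life expectancies and PFS durations of the order reported for these
strategies, and are treated as fixed study conditions; costs and utilities
are mildly seed-jittered around Swiss-plausible values so that different
seeds give different, always-valid configurations.

`generate_ipd()` draws event times from a chosen family with purely
administrative censoring at a fixed follow-up (the 2-year trial cutoff);
random dropout is not modelled. `emulate_digitized_curve()` samples the KM
step function on a coordinate grid, optionally adds truncated-normal noise
on the probability scale (a digitizer's error is small and bounded) and
projects back to monotonicity isotonically, since a published curve is
non-increasing and monotonicity must be restored before fitting.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: patient-level covariates (age, histology,
PD-L1 distribution), informative censoring and dropout, within-trial
correlation between PFS and OS of the same patients, treatment-effect
waning, and real digitization pathologies (axis misreads, plateau
misreads). The pipeline's correctness on synthetic data is a necessary,
not sufficient, condition for validity on trial data.

A note on curve ordering: the generator targets PFS ≤ OS, but with a
lognormal PFS and an exponential OS the inequality necessarily fails as
t → 0⁺ (the lognormal survivor approaches 1 faster than any power of t).
The configuration validator therefore checks the ordering on the model's
actual monthly evaluation grid, where the defaults satisfy it; sub-month
crossings are immaterial at 1-month cycles.

## Numerical choices and problem sizes

* Occupancy conservation is asserted at 1e-10 per cycle; OS conservation
  and tunnel-age bookkeeping at floating-point precision.
* The accrual path is validated against an independent spreadsheet-style
  recomputation on a 3-cycle model at 1e-10, and against a closed-form
  geometric-series expression for discounted life years at 1e-8.
* The cohort engine is validated against a 200,000-walker microsimulation
  (exact multinomial count sampling per cycle, so each state count is
  marginally binomial and the 3-standard-error band is exact).
* Parameter recovery uses n = 5,000 (5% tolerance) and family selection
  100 replicates at n = 1,000 (≥ 90 expected correct); the one-way and
  probabilistic test fixtures run at a 60-cycle horizon, chosen so the
  full suite completes in well under a minute of simulation per property.
* Exact criterion ties in model selection break by parameter count, then
  by the fixed family order — deterministic, documented, and tested.

## Known limitations

Independent survival-curve modelling prevents varying a treatment *effect*
directly in sensitivity analyses (only each arm's own parameters move);
second-line progression as a fixed threshold ignores 2L PFS heterogeneity;
the uniform death allocation, while structurally exact for OS, makes the
PFS/PD death split an assumption rather than an estimate; no
value-of-information analysis, no partitioned-survival mode, and no
indirect treatment comparison across trials are provided — the last being
deliberate, since a failed PH diagnostic is this model's reason for
existing in its three-strategy form.
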