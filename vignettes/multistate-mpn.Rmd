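---
title: "Multistate modelling of ET and pre-PMF progression with mpnstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate modelling of ET and pre-PMF progression with mpnstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mpnstate)
```

## The model and its assumptions

`mpnstate` treats the natural history of essential thrombocythemia (ET)
and prefibrotic primary myelofibrosis (pre-PMF) as a continuous-time
Markov process on five states — Diagnosis, Thrombosis, Overt
myelofibrosis (MF), Blast phase (BP), Death — connected by ten
transitions forming a progressive directed acyclic graph.  Three
modelling assumptions do the heavy lifting:

1. **Clock-forward (Markov) time scale.**  Every transition intensity is
   a function of time since diagnosis, not time since entering the
   current state.  A patient who develops thrombosis at year 3 is, from
   then on, exposed to the thrombosis-state exit intensities evaluated at
   their running disease clock.  This is what makes the process Markov;
   a semi-Markov (clock-reset) variant is deliberately out of scope.
2. **Progressive disease.**  No state is ever re-entered; remissions are
   not modelled.  Validation rejects histories that revisit a state or
   move along a non-edge (e.g. BlastPhase to OvertMF).
3. **Proportional hazards within transition.**  Each transition r → s
   has intensity `q_rs(t|x) = q0_rs(t) exp(beta' x)` with its own
   baseline and coefficients; nothing is shared across transitions, so
   the likelihood separates and each transition can be maximized alone.

The likelihood is the standard censored counting-process form.  Each
long-format record (one transition, one sojourn, risk window
`(tstart, tstop]`) contributes the cumulative intensity over its window,
and event records additionally contribute the log intensity at the event
time.  The value is invariant to splitting records at interior times —
a property the test suite checks to 1e-12 — which is what licenses the
long-format representation in the first place.

## Baseline families

Three baselines are supported: exponential (`q0 = lambda`), Weibull
(`q0 = lambda * gamma * t^(gamma-1)`), and Gompertz
(`q0 = lambda * exp(gamma * t)`).  Weibull with `gamma = 1` and Gompertz
with `gamma = 0` both reduce to the exponential, so the exponential fit
is a nested sanity reference for either richer family (the suite checks
the implied log-likelihood ordering).  The non-monotone,
rise-then-fall curves typical of transient destination states need no
non-monotone baseline: they arise from the process itself, because
probability mass flows onward out of the destination.

`msm_fit()` maximizes each transition's likelihood by BFGS on
log-transformed positive parameters (rate, Weibull shape), with the
Gompertz shape unconstrained.  Convergence uses a relative tolerance of
1e-12 with at most 500 iterations; standard errors come from the
numerical Hessian at the optimum.  Transitions with zero observed events
are never dropped silently: they are flagged inestimable and their rate
pinned at a documented floor of 1e-10 per year.

## Probabilities

Transition-probability matrices solve the Kolmogorov forward equations
`dP(s,t)/dt = P(s,t) Q(t)` with `P(s,s) = I`, using an adaptive solver
at `rtol = 1e-8`, `atol = 1e-10`.  Two numerical choices are worth
stating:

- **No row renormalization.**  Row sums drifting from 1 beyond 1e-5 are
  raised as an error rather than hidden; drift is a diagnostic of solver
  failure, not noise to be cleaned.
- **Singularity floor.**  Weibull baselines with shape below 1 have an
  infinite (but integrable) intensity at t = 0.  Inside the solver the
  intensity is evaluated at `max(t, 1e-8)`; the perturbation to the
  cumulative intensity is orders of magnitude below the solver
  tolerances, and the exact matrix-exponential cross-check for constant
  intensities is unaffected.

State occupation is the initial distribution (all mass in Diagnosis by
default) propagated by `P(0, t)`; its Diagnosis entry is the
"event-free" probability and its Death entry the overall probability of
having died.  The Aalen-Johansen estimator provides the nonparametric
companion: Nelson-Aalen increments `d/Y` at each observed transition
time, accumulated through the product integral, evaluated as
right-continuous step functions.  Tied event times across subjects are
rejected with advice to pre-jitter by a small epsilon (1e-6 years is
plenty); both the likelihood and the product integral require a strict
ordering, and the generator produces ties with probability zero.

For death "via" an intermediate state, two distinct quantities are often
conflated: the probability of the full path (diagnosis, then the
intermediate state, then death by t) and the conditional probability of
death given occupancy of the intermediate state.  The package exposes
the ingredients for both — `P(0,t)` entries give path-marginal
occupations, and `transition_probability(model, s = t_entry, ...)` rows
give the conditional curves from any landmark time.

## The synthetic-cohort generator

No patient-level ET/pre-PMF data are public, so the generator is a
first-class module, not a test fixture.  It simulates the exact process
the model assumes: starting at diagnosis, a unit-exponential deviate is
drawn and the total-exit cumulative intensity inverted for the exit
time (closed form when all exits are exponential, bracketed root finding
otherwise), the destination drawn proportionally to the exit intensities
at that time, and the path stopped at absorption or censoring.

The two presets are calibrated to published cohort-level anchors:

- total Diagnosis-exit intensity from the closed-form inversion of the
  10-year event-free probability — 70% (ET-like) and 50% (pre-PMF-like);
- thrombosis / MF / BP destination shares proportional to the reported
  direct-transition counts (101/29/6 in ET, 53/51/15 in pre-PMF);
- the Diagnosis-to-death share solved numerically at construction so the
  model's *total* 10-year death occupation equals the reported 15%
  (ET-like) and 30% (pre-PMF-like).  A first-transition-only calibration
  would overshoot, since indirect deaths through the transient states
  add a few points on top of the direct ones.

Post-diagnosis intensities are package defaults, fixed once: death runs
fast from blast phase (0.6/year) and overt MF (0.1/year) and
several-fold above the direct diagnosis-to-death rate after thrombosis
(0.055/year), with small rates for the remaining evolutions.  Censoring
is administrative at 30 years plus independent exponential dropout at
0.01/year — the source registries' censoring pattern is unpublished, so
these are explicit package choices.

Preset covariates (age, sex, WBC, platelets, JAK2V617F, cardiovascular
risk, prior thrombosis) follow `default_covariate_spec()` and carry *no*
hazard effects by default.  That keeps the occupancy calibration exact
and is the main deliberate departure from realism: in real cohorts the
IPSET factors are prognostic, so hazard ratios estimated on preset data
hover around 1.  Covariate effects are exercised through explicit
configurations instead (the test suite recovers a true hazard ratio of
2 and a doubled incidence rate from `beta = log 2` configurations).
Consequences for interpretation: passing tests demonstrate the
estimators recover the generating process — rates, coefficients,
occupation curves — under the model's own assumptions; they say nothing
about model adequacy for real registry data, where event-time reporting,
therapy effects (not modelled here), non-proportional hazards, and
semi-Markov dynamics can all intrude.

## Risk scores

IPSET-survival (age >= 60: 2 points; WBC >= 11: 1; prior thrombosis: 1;
low = 0, intermediate = 1–2, high = 3–4) and IPSET-thrombosis (age > 60:
1; cardiovascular risk factors: 1; prior thrombosis: 2; JAK2V617F: 2;
low < 2, intermediate = 2, high > 2) are declared in a single constants
table taken from the scores' original publications; note the
deliberately different age-threshold inclusivity between the two scores.
`assign_groups()` produces reference-coded dummies (low as reference)
for `cox_transition()`, which refuses covariates without variation
rather than returning a degenerate fit.

## Problem sizes and tolerances used in the test suite

The suite's simulation sizes are package choices balancing statistical
resolution against runtime: n = 10,000 for closed-form Monte-Carlo
checks (3 standard errors), n = 2,000 x 200 replicates for
rate-recovery and Wald-coverage checks (coverage accepted in [90%,
98%]), n = 3,000–4,000 for Cox and covariate-effect recovery (15%
relative tolerance), and the published cohort sizes (791, 382) for the
calibration round trips (±3–4 percentage points, the Monte-Carlo
resolution those sizes afford).  Oracles are independent of the code
paths they check: matrix exponentials for constant-intensity forward
solutions, adaptive quadrature for Weibull likelihood terms, hand
product-integrals and a hand-written Breslow partial likelihood for the
nonparametric and Cox paths, and closed-form competing-risks formulas
for the generator.

## Known limitations

- Clock-forward hazards only; no semi-Markov sojourn-time effects.
- Exact event times are assumed (no interval censoring); simultaneous
  events must be pre-jittered.
- No frailty or random effects; no spline baselines.
- Aalen-Johansen confidence bands are not provided in this version.
- Therapy (cytoreduction) is not modelled, and the preset covariate
  distributions are package defaults, not estimates of any registry's
  baseline table.
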