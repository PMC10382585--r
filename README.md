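# mpnstate

Multistate survival analysis of disease progression in the chronic
myeloproliferative neoplasms **essential thrombocythemia (ET)** and
**prefibrotic primary myelofibrosis (pre-PMF)**.

Patients with ET or pre-PMF start at diagnosis and may experience an
incident thrombosis, evolve to overt myelofibrosis (MF), transform to
blast phase (BP), and die — in any order the disease biology allows.
Analyses that look at one endpoint at a time miss how these intermediate
states compete with and condition each other.  `mpnstate` implements the
multistate view for biostatisticians and clinical epidemiologists working
on these (or structurally similar, progressive) diseases.

## The model

The disease history is a continuous-time Markov process on five states

```
Diagnosis --> {Thrombosis, OvertMF, BlastPhase, Death}
Thrombosis --> {OvertMF, BlastPhase, Death}
OvertMF   --> {BlastPhase, Death}
BlastPhase --> Death
```

— a progressive directed acyclic graph with ten transitions and Death the
sole absorbing state.  Each transition r → s carries a parametric
intensity on the clock-forward scale (t = years since diagnosis)

    q_rs(t | x) = q0_rs(t) · exp(β'x),

with exponential, Weibull, or Gompertz baseline `q0` and
proportional-hazards covariate effects.  The package provides:

- **Data preparation** — wide per-patient histories, validation against
  the transition graph, and expansion to the counting-process long format
  (one row per at-risk transition per sojourn, with delayed entry).
- **Maximum-likelihood fitting** (`msm_fit`) of all ten intensities from
  censored histories, with Wald covariance from the numerical Hessian;
  per-transition Cox regression (`cox_transition`, Breslow ties) as the
  semi-parametric companion.
- **Probabilities** — transition-probability matrices P(s, t) by solving
  the Kolmogorov forward equations dP/dt = P·Q(t), state-occupation
  curves (the Diagnosis entry is the "event-free" probability), and the
  nonparametric Aalen-Johansen product-integral estimator.
- **Risk scores** — IPSET-thrombosis and IPSET-survival points and
  low/intermediate/high groups, ready for per-transition hazard-ratio
  estimation.
- **Synthetic cohorts** — a generator with calibrated ET-like (n = 791)
  and pre-PMF-like (n = 382) presets anchored to published summary
  probabilities (70% vs 50% event-free and 15% vs 30% dead at 10 years),
  so every stage is testable without patient-level data.

## Worked example

```r
library(mpnstate)

cfg    <- et_preset(n_subjects = 791)      # calibrated ET-like generator
cohort <- simulate_cohort(cfg)             # wide disease histories
tab    <- transition_count_table(cohort)   # descriptive per-transition table
tab[, c("trans", "from", "to", "n_entered", "n_moved", "percent")]
```

```
 trans       from         to n_entered n_moved percent
     1  Diagnosis Thrombosis       791     260    32.9
     2  Diagnosis    OvertMF       791      64     8.1
     3  Diagnosis BlastPhase       791      12     1.5
     4  Diagnosis      Death       791     113    14.3
     5 Thrombosis    OvertMF       260      10     3.8
     6 Thrombosis BlastPhase       260       7     2.7
     7 Thrombosis      Death       260     132    50.8
     8    OvertMF BlastPhase        74      11    14.9
     9    OvertMF      Death        74      46    62.2
    10 BlastPhase      Death        30      30   100.0
```

Each row is one transition: how many subjects ever entered the source
state, how many took that exit, and the percentage among entrants
(here over the full 30-year synthetic follow-up, so the thrombosis
fraction is far above its 10-year value).  Fit the model and read off
occupation probabilities:

```r
fit <- msm_fit(to_long(cohort), family = "exponential")
occ <- predict(fit, times = c(5, 10, 20))
round(occ$probs, 3)
```

```
     Diagnosis Thrombosis OvertMF BlastPhase Death
[1,]     0.842      0.080   0.017      0.002 0.060
[2,]     0.708      0.127   0.025      0.002 0.138
[3,]     0.502      0.162   0.026      0.002 0.307
```

At 10 years, 70.8% of this simulated ET-like cohort is still event-free
and 13.8% has died — the fitted round trip recovers the preset's
calibration anchors (70% and 15%) up to sampling noise.  Risk-group
annotation for per-transition hazard ratios:

```r
scored <- assign_groups(cohort, "ipset_thrombosis")
attr(scored, "group_sizes")
#>  low intermediate  high
#>  231          205   355
cox_transition(to_long(scored), 1, c("intermediate", "high"))
```

`run_pipeline()` chains all stages (simulate → score → fit → predict →
report) and writes the tables, fitted-model JSON, and figures to a
directory, with the seed and a config hash in every output header.

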