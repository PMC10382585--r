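# Fixtures built in code: deterministic cohorts with prescribed transition
# counts, and small utilities shared across test files.

# wide cohort skeleton: everyone censored at `censor`
blank_cohort <- function(n, censor = 25) {
  data.frame(subject_id = sprintf("p%04d", seq_len(n)),
             thrombosis_time = NA_real_, mf_time = NA_real_,
             bp_time = NA_real_, death_time = NA_real_,
             censor_time = censor + seq_len(n) * 1e-4,
             stringsAsFactors = FALSE)
}

# ET-like descriptive fixture: 791 subjects; 101 to thrombosis, of whom 21
# die (median sojourn 4y), 3 evolve to MF and 1 to BP; 29 direct MF; 6
# direct BP (so BP is entered 7 times, 6 of them directly); 30 direct deaths.
fixture_counts_et <- function() {
  coh <- blank_cohort(791)
  thr <- 1:101
  coh$thrombosis_time[thr] <- 1 + thr * 1e-3
  d <- 1:21   # thrombosis -> death, sojourns centred on 4y
  coh$death_time[d] <- coh$thrombosis_time[d] + 4 + (d - 11) * 0.01
  coh$censor_time[d] <- NA
  coh$mf_time[22:24] <- coh$thrombosis_time[22:24] + 4.7 + (0:2) * 0.01
  coh$bp_time[25] <- coh$thrombosis_time[25] + 5.2
  mf <- 102:130
  coh$mf_time[mf] <- 3 + mf * 1e-3
  bp <- 131:136
  coh$bp_time[bp] <- 2 + bp * 1e-3
  dd <- 137:166
  coh$death_time[dd] <- 6 + dd * 1e-3
  coh$censor_time[dd] <- NA
  coh
}

# pre-PMF-like descriptive fixture: 382 subjects; 53 to thrombosis, 51
# direct MF, 15 direct BP.
fixture_counts_prepmf <- function() {
  coh <- blank_cohort(382)
  coh$thrombosis_time[1:53] <- 1 + (1:53) * 1e-3
  coh$mf_time[54:104] <- 2 + (54:104) * 1e-3
  coh$bp_time[105:119] <- 3 + (105:119) * 1e-3
  coh
}

# thrombosis-sojourn fixture: 105 subjects reach thrombosis, 12 die after
fixture_thrombosis_deaths <- function() {
  coh <- blank_cohort(105)
  coh$thrombosis_time <- 1 + seq_len(105) * 1e-3
  coh$death_time[1:12] <- 5 + (1:12) * 1e-3
  coh$censor_time[1:12] <- NA
  coh
}

# all-exponential model on the default structure with given rates (trans 1..10)
exp_model <- function(rates) {
  multistate_model(transition_structure(),
                   lapply(rates, function(r) hazard_spec("exponential", r)))
}

# a model where effectively only some Diagnosis exits are active
# (inactive transitions get a negligible rate; hazard rates must be > 0)
sparse_exp_model <- function(active, eps = 1e-12) {
  rates <- rep(eps, 10)
  rates[as.integer(names(active))] <- unname(active)
  exp_model(rates)
}

# model with randomly drawn families and parameters on the default DAG
random_model <- function(seed, families = c("exponential", "weibull",
                                            "gompertz")) {
  set.seed(seed)
  hz <- lapply(1:10, function(k) {
    fam <- sample(families, 1)
    switch(fam,
      exponential = hazard_spec("exponential", runif(1, 0.005, 0.1)),
      weibull = hazard_spec("weibull", runif(1, 0.005, 0.1),
                            shape = runif(1, 0.7, 1.8)),
      gompertz = hazard_spec("gompertz", runif(1, 0.005, 0.1),
                             shape = runif(1, -0.05, 0.08)))
  })
  multistate_model(transition_structure(), hz)
}

expect_valid_cohort <- function(cohort, ts = transition_structure()) {
  v <- validate_cohort(cohort, ts)
  expect_identical(nrow(v), 0L)
}
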