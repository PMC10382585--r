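test_that("exit-time inversion matches closed forms and a brute-force root", {
  # single exponential exit lambda = 0.2, E = 0.5 -> exit at 2.5y
  sp <- list(hazard_spec("exponential", 0.2))
  expect_equal(mpnstate:::solve_exit_time(sp, 1, u = 0, E = 0.5), 2.5)

  # Weibull with shape 2 and unit cumulative hazard at 1y: E = 1 -> t = 1
  spw <- list(hazard_spec("weibull", rate = 1, shape = 2))
  expect_equal(mpnstate:::solve_exit_time(spw, 1, u = 0, E = 1), 1,
               tolerance = 1e-9)

  # mixed-family exit from a late entry time, against a grid root-finder
  specs <- list(hazard_spec("weibull", 0.3, shape = 1.7),
                hazard_spec("gompertz", 0.1, shape = 0.05))
  u <- 1.5; E <- 0.8
  cum <- function(t) sum(vapply(specs, function(s)
    mpnstate:::baseline_cumhaz(s, t) - mpnstate:::baseline_cumhaz(s, u),
    numeric(1)))
  grid <- seq(u, 20, by = 1e-5)
  brute <- grid[which.max(vapply(grid, cum, numeric(1)) >= E)]
  t_impl <- mpnstate:::solve_exit_time(specs, c(1, 1), u, E)
  expect_equal(t_impl, brute, tolerance = 1e-4)
  expect_equal(cum(t_impl), E, tolerance = 1e-10)
})

test_that("destination choice splits by relative intensity", {
  # two equal exponential exits out of Diagnosis: 50/50 split
  mm <- sparse_exp_model(c("2" = 0.1, "3" = 0.1))
  cfg <- generator_config(4000, mm, admin_censor_time = 1e6, seed = 21)
  coh <- simulate_cohort(cfg)
  n_mf <- sum(!is.na(coh$mf_time))
  n_bp <- sum(!is.na(coh$bp_time))
  expect_equal(n_mf / (n_mf + n_bp), 0.5,
               tolerance = 3 * sqrt(0.25 / 4000) / 0.5)
})

test_that("simulated cohorts are reproducible and validate", {
  cfg <- et_preset(n_subjects = 200, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_valid_cohort(c1)
  c3 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(c1, c3))
})

test_that("mean exit time matches the exponential closed form", {
  # single active exit at rate 0.1/year, no censoring: mean exit 10y
  mm <- sparse_exp_model(c("4" = 0.1))
  cfg <- generator_config(10000, mm, admin_censor_time = 1e7, seed = 3)
  coh <- simulate_cohort(cfg)
  expect_true(all(!is.na(coh$death_time)))
  se <- 10 / sqrt(10000)
  expect_equal(mean(coh$death_time), 10, tolerance = 3 * se / 10)
})

test_that("a tiny administrative horizon censors essentially everyone", {
  mm <- sparse_exp_model(c("1" = 0.01, "4" = 0.01))
  cfg <- generator_config(500, mm, admin_censor_time = 0.001, seed = 4)
  coh <- simulate_cohort(cfg)
  expect_true(mean(!is.na(coh$censor_time)) > 0.99)
})

test_that("first-transition frequencies match competing-risks closed forms", {
  lam <- c(0.05, 0.02, 0.004, 0.01)
  mm <- sparse_exp_model(stats::setNames(lam, 1:4))
  horizon <- 30
  cfg <- generator_config(10000, mm, admin_censor_time = horizon, seed = 12)
  coh <- simulate_cohort(cfg)
  # downstream rates are negligible, so first moves are the recorded entries
  Lam <- sum(lam)
  p_first <- lam / Lam * (1 - exp(-Lam * horizon))
  obs <- c(mean(!is.na(coh$thrombosis_time)), mean(!is.na(coh$mf_time)),
           mean(!is.na(coh$bp_time)), mean(!is.na(coh$death_time)))
  for (j in 1:4) {
    se <- sqrt(p_first[j] * (1 - p_first[j]) / 10000)
    expect_equal(obs[j], p_first[j], tolerance = 3 * se / p_first[j])
  }
})

test_that("doubling the linear predictor doubles the incidence rate", {
  ts <- transition_structure()
  hz <- rep(list(hazard_spec("exponential", 1e-12)), 10)
  hz[[4]] <- hazard_spec("exponential", 0.02, beta = c(x = log(2)))
  mm <- multistate_model(ts, hz)
  covspec <- function(n) data.frame(x = rep(c(0, 1), length.out = n))
  cfg <- generator_config(8000, mm, covariate_spec = covspec,
                          admin_censor_time = 10, seed = 31)
  coh <- simulate_cohort(cfg)
  rate <- function(sub) {
    ev <- !is.na(sub$death_time)
    exposure <- ifelse(ev, sub$death_time, sub$censor_time)
    sum(ev) / sum(exposure)
  }
  rr <- rate(coh[coh$x == 1, ]) / rate(coh[coh$x == 0, ])
  expect_equal(rr, 2, tolerance = 0.15)
})

test_that("calibration closed forms invert the targets exactly", {
  # single destination, event-free 0.7 at 10y: total rate -ln(0.7)/10
  r <- calibrate_exponential_exits(0.7, c(Death = 0.3), horizon = 10)
  expect_equal(attr(r, "total"), -log(0.7) / 10)
  expect_equal(attr(r, "unassigned"), 0)
  expect_equal(unname(r["Death"]), -log(0.7) / 10)

  # event-free 0.5 split equally over two destinations
  r2 <- calibrate_exponential_exits(0.5, c(A = 0.25, B = 0.25), horizon = 10)
  expect_equal(unname(r2["A"]), -log(0.5) / 20)
  expect_equal(unname(r2["A"]), unname(r2["B"]))

  # arbitrary feasible 3-destination target: forward check to 1e-12
  tgt <- c(a = 0.17, b = 0.08, c = 0.31)
  ef <- 0.44
  r3 <- calibrate_exponential_exits(ef, tgt, horizon = 12)
  Lam <- attr(r3, "total")
  expect_equal(exp(-Lam * 12), ef, tolerance = 1e-12)
  fwd <- as.vector(r3) / Lam * (1 - exp(-Lam * 12))
  expect_equal(fwd, unname(tgt), tolerance = 1e-12)

  expect_error(calibrate_exponential_exits(0.6, c(A = 0.5), 10),
               "infeasible")
  expect_error(calibrate_exponential_exits(1.2, c(A = 0.1), 10), "event_free")
})
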