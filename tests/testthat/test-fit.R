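one_edge_structure <- function() {
  transition_structure(state_space(c("A", "B"), "B"), cbind("A", "B"))
}

one_edge_model <- function(spec) multistate_model(one_edge_structure(),
                                                  list(spec))

test_that("negative log-likelihood matches closed forms", {
  d <- data.frame(subject_id = "s", trans = 1, from = "A", to = "B",
                  tstart = 0, tstop = 2, status = 1L)
  mm <- one_edge_model(hazard_spec("exponential", 0.5))
  expect_equal(neg_log_likelihood(mm, d), 1 + log(2))
  d0 <- d; d0$status <- 0L
  expect_equal(neg_log_likelihood(mm, d0), 1)
})

test_that("Weibull likelihood term matches adaptive quadrature", {
  spec <- hazard_spec("weibull", rate = 0.3, shape = 1.7)
  d <- data.frame(subject_id = "s", trans = 1, from = "A", to = "B",
                  tstart = 1, tstop = 4, status = 1L)
  mm <- one_edge_model(spec)
  cumhaz <- stats::integrate(function(t) 0.3 * 1.7 * t^0.7, 1, 4,
                             rel.tol = 1e-12)$value
  oracle <- cumhaz - log(0.3 * 1.7 * 4^0.7)
  expect_equal(neg_log_likelihood(mm, d), oracle, tolerance = 1e-9)
})

test_that("likelihood is invariant to splitting records at interior times", {
  set.seed(42)
  coh <- simulate_cohort(et_preset(n_subjects = 120, seed = 42))
  long <- to_long(coh)
  mm <- et_preset(n_subjects = 1)$true_model
  base <- neg_log_likelihood(mm, long)
  split_at <- function(long, frac) {
    mid <- long$tstart + frac * (long$tstop - long$tstart)
    first <- long; first$tstop <- mid; first$status <- 0L
    second <- long; second$tstart <- mid
    rbind(first, second)
  }
  expect_equal(neg_log_likelihood(mm, split_at(long, 0.37)), base,
               tolerance = 1e-12)
  # also on a Weibull/Gompertz model (time-varying baselines)
  hz <- c(rep(list(hazard_spec("weibull", 0.02, shape = 1.4)), 4),
          rep(list(hazard_spec("gompertz", 0.03, shape = 0.04)), 6))
  mm2 <- multistate_model(transition_structure(), hz)
  base2 <- neg_log_likelihood(mm2, long)
  expect_equal(neg_log_likelihood(mm2, split_at(long, 0.61)), base2,
               tolerance = 1e-12)
})

test_that("exponential MLE equals events over person-time", {
  # 10 events in 200 person-years -> rate 0.05/year
  d <- data.frame(subject_id = sprintf("s%d", 1:100), trans = 1, from = "A",
                  to = "B", tstart = 0, tstop = 2,
                  status = rep(c(1L, 0L), c(10, 90)))
  fit <- msm_fit(d, structure = one_edge_structure(), family = "exponential")
  expect_equal(fit$model$hazards[[1]]$rate, 0.05, tolerance = 1e-6)
  expect_true(fit$converged)
  # analytic SE of log rate is 1/sqrt(events)
  expect_equal(sqrt(diag(fit$details[[1]]$vcov))[["log_rate"]],
               1 / sqrt(10), tolerance = 1e-3)
})

test_that("total log-likelihood separates over transitions", {
  coh <- simulate_cohort(et_preset(n_subjects = 250, seed = 8))
  long <- to_long(coh)
  fit <- msm_fit(long, family = "exponential")
  per_edge <- vapply(1:10, function(k) {
    f1 <- msm_fit(long[long$trans == k, ],
                  structure = transition_structure(),
                  family = "exponential")
    f1$details[[k]]$loglik
  }, numeric(1))
  expect_equal(fit$loglik, sum(per_edge), tolerance = 1e-8)
  expect_equal(fit$loglik,
               -neg_log_likelihood(fit$model, long), tolerance = 1e-6)
})

test_that("richer families never fit worse than their exponential special case", {
  coh <- simulate_cohort(et_preset(n_subjects = 400, seed = 13))
  long <- to_long(coh)
  f_exp <- msm_fit(long, family = "exponential")
  f_wei <- msm_fit(long, family = "weibull")
  f_gom <- msm_fit(long, family = "gompertz")
  expect_true(f_wei$loglik >= f_exp$loglik - 1e-6)
  expect_true(f_gom$loglik >= f_exp$loglik - 1e-6)
  # shape at its null value reduces both families to the exponential
  d <- long[long$trans == 1, ]
  mm_e <- one_edge_model(hazard_spec("exponential", 0.03))
  mm_w <- one_edge_model(hazard_spec("weibull", 0.03, shape = 1))
  mm_g <- one_edge_model(hazard_spec("gompertz", 0.03, shape = 0))
  d$trans <- 1
  expect_equal(neg_log_likelihood(mm_w, d), neg_log_likelihood(mm_e, d))
  expect_equal(neg_log_likelihood(mm_g, d), neg_log_likelihood(mm_e, d))
})

test_that("transitions without events are reported inestimable", {
  coh <- blank_cohort(40)
  coh$death_time[1:5] <- 1 + (1:5) * 0.1
  coh$censor_time[1:5] <- NA
  fit <- msm_fit(to_long(coh), family = "exponential")
  expect_true(fit$edges$inestimable[1])   # no thrombosis events
  expect_false(fit$edges$inestimable[4])  # direct deaths observed
  expect_identical(fit$model$hazards[[1]]$rate, 1e-10)
})

test_that("single-transition parameter recovery at n = 2000", {
  rates <- c(0.05, 0.02, 0.004, 0.01, 0.03, 0.01, 0.02, 0.04, 0.06, 0.5)
  cfg <- generator_config(2000, exp_model(rates), admin_censor_time = 30,
                          seed = 19)
  fit <- msm_fit(to_long(simulate_cohort(cfg)), family = "exponential")
  est <- vapply(fit$model$hazards, function(h) h$rate, numeric(1))
  expect_true(all(abs(est / rates - 1) < 0.35))
  expect_true(all(abs(est[1:4] / rates[1:4] - 1) < 0.15))
})

test_that("Weibull fit agrees with an independent parametric fitter", {
  skip_if_not_installed("flexsurv")
  hz <- rep(list(hazard_spec("exponential", 1e-12)), 10)
  hz[[4]] <- hazard_spec("weibull", 0.02, shape = 1.5)
  cfg <- generator_config(1500, multistate_model(transition_structure(), hz),
                          admin_censor_time = 30, seed = 23)
  long <- to_long(simulate_cohort(cfg))
  fit <- msm_fit(long, family = "weibull")
  d4 <- long[long$trans == 4, ]
  ref <- flexsurv::flexsurvreg(
    survival::Surv(tstart, tstop, status) ~ 1, data = d4,
    dist = "weibullPH")
  ref_shape <- unname(ref$res["shape", "est"])
  ref_rate <- unname(ref$res["scale", "est"])
  expect_equal(fit$model$hazards[[4]]$shape, ref_shape, tolerance = 1e-3)
  expect_equal(fit$model$hazards[[4]]$rate, ref_rate, tolerance = 1e-3)
})

test_that("covariate coefficients are recovered in the parametric fit", {
  ts <- transition_structure()
  hz <- rep(list(hazard_spec("exponential", 1e-12)), 10)
  hz[[1]] <- hazard_spec("exponential", 0.03, beta = c(x = log(2)))
  mm <- multistate_model(ts, hz)
  covspec <- function(n) data.frame(x = rep(c(0, 1), length.out = n))
  cfg <- generator_config(3000, mm, covariate_spec = covspec,
                          admin_censor_time = 20, seed = 29)
  long <- to_long(simulate_cohort(cfg))
  fit <- msm_fit(long, family = "exponential",
                 covariates = list("1" = "x"))
  beta <- fit$model$hazards[[1]]$beta[["x"]]
  expect_equal(exp(beta), 2, tolerance = 0.15)
})
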