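test_that("forward solution matches the matrix exponential for constant intensities", {
  skip_if_not_installed("Matrix")
  set.seed(1)
  for (rep in 1:3) {
    rates <- runif(10, 0.002, 0.2)
    mm <- exp_model(rates)
    Q <- mpnstate:::intensity_matrix(mm, 0)
    for (t in c(2, 10, 25)) {
      oracle <- as.matrix(Matrix::expm(Q * t))
      pp <- transition_probability(mm, times = t)
      expect_equal(unname(pp$P[1, , ]), unname(oracle), tolerance = 1e-8)
    }
  }
})

test_that("competing exponential exits follow the closed form", {
  mm <- sparse_exp_model(c("2" = 0.1, "3" = 0.1))
  pp <- transition_probability(mm, times = 10)
  expect_equal(pp$P[1, "Diagnosis", "Diagnosis"], exp(-2), tolerance = 1e-6)
  expect_equal(pp$P[1, "Diagnosis", "Diagnosis"], 0.13534, tolerance = 1e-4)
  expect_equal(pp$P[1, "Diagnosis", "OvertMF"], 0.43233, tolerance = 1e-3)
})

test_that("a degenerate grid returns the identity and t = 0 keeps the initial law", {
  mm <- random_model(3)
  pp <- transition_probability(mm, s = 1.5, times = 1.5)
  expect_equal(unname(pp$P[1, , ]), diag(5), tolerance = 1e-12)
  init <- c(0.6, 0.2, 0.1, 0.05, 0.05)
  oc <- state_occupation(mm, times = 0, initial = init)
  expect_equal(unname(oc$probs[1, ]), init, tolerance = 1e-10)
})

test_that("occupation matches the calibrated closed form at the horizon", {
  lam <- -log(0.7) / 10
  mm <- sparse_exp_model(c("4" = lam))
  oc <- state_occupation(mm, times = 10)
  expect_equal(unname(oc$probs[1, "Diagnosis"]), 0.7, tolerance = 1e-6)
})

test_that("Chapman-Kolmogorov holds for random mixed-family models", {
  for (seed in 1:4) {
    mm <- random_model(seed)
    s <- 0; t <- 6; u <- 18
    P_su <- transition_probability(mm, s = s, times = u)$P[1, , ]
    P_st <- transition_probability(mm, s = s, times = t)$P[1, , ]
    P_tu <- transition_probability(mm, s = t, times = u)$P[1, , ]
    expect_equal(unname(P_su), unname(P_st %*% P_tu), tolerance = 1e-6)
  }
})

test_that("rows sum to one and absorbing mass is monotone", {
  for (seed in 5:7) {
    mm <- random_model(seed)
    tg <- seq(0, 30, by = 0.5)
    pp <- transition_probability(mm, times = tg)
    expect_true(max(abs(apply(pp$P, c(1, 2), sum) - 1)) < 1e-6)
    expect_true(all(pp$P >= -1e-9 & pp$P <= 1 + 1e-9))
    death <- pp$P[, "Diagnosis", "Death"]
    expect_true(all(diff(death) > -1e-9))
    oc <- state_occupation(mm, times = tg)
    expect_true(max(abs(rowSums(oc$probs) - 1)) < 1e-6)
    expect_true(all(diff(oc$probs[, "Death"]) > -1e-9))
  }
})

test_that("the ET-like preset yields a non-monotone direct thrombosis curve", {
  mm <- et_preset(n_subjects = 1)$true_model
  tg <- seq(0, 30, by = 0.25)
  pp <- transition_probability(mm, times = tg)
  thr <- pp$P[, "Diagnosis", "Thrombosis"]
  peak <- which.max(thr)
  expect_gt(peak, 1)
  expect_lt(peak, length(tg))          # interior maximum
  expect_gt(max(thr) - thr[length(tg)], 0.005)  # genuine decline after it
  oc <- state_occupation(mm, times = tg)
  expect_true(all(diff(oc$probs[, "Death"]) > -1e-9))
  occ_thr <- oc$probs[, "Thrombosis"]
  p <- which.max(occ_thr)
  expect_true(p > 1 && p < length(tg))
  expect_true(all(diff(occ_thr[1:p]) > -1e-9))
  expect_true(all(diff(occ_thr[p:length(tg)]) < 1e-9))
})

test_that("Aalen-Johansen reproduces the hand product integral", {
  coh <- data.frame(subject_id = c("A", "B", "C"),
                    thrombosis_time = c(NA, 2, NA), mf_time = NA,
                    bp_time = NA, death_time = c(1, NA, NA),
                    censor_time = c(NA, 3, 4))
  aj <- aalen_johansen(coh, times = 2.5)
  # at t=1: death with Y=3 -> (2/3, 0, 1/3); at t=2: thrombosis with Y=2
  expect_equal(unname(aj$probs[1, c("Diagnosis", "Thrombosis", "Death")]),
               c(1 / 3, 1 / 3, 1 / 3), tolerance = 1e-12)
  # Nelson-Aalen cumulative hazards: 1/3 for D->Death, 1/2 for D->Thromb
  ch <- aj$cumhaz
  expect_equal(ch$cumhaz[ch$trans == 4 & ch$time == 1], 1 / 3)
  expect_equal(max(ch$cumhaz[ch$trans == 1]), 1 / 2)
})

test_that("with one transition the AJ death curve is one minus Kaplan-Meier", {
  set.seed(9)
  n <- 150
  coh <- blank_cohort(n)
  ev <- rexp(n, 0.1)
  cens <- pmin(runif(n, 0, 15), 20)
  died <- ev <= cens
  coh$death_time[died] <- ev[died]
  coh$censor_time[died] <- NA
  coh$censor_time[!died] <- cens[!died]
  coh$death_time <- coh$death_time + seq_len(n) * 1e-9  # break ties
  tg <- c(2, 5, 8, 12)
  aj <- aalen_johansen(coh, times = tg)
  km <- survival::survfit(survival::Surv(
    ifelse(is.na(coh$death_time), coh$censor_time, coh$death_time),
    !is.na(coh$death_time)) ~ 1)
  km_at <- summary(km, times = tg)$surv
  expect_equal(unname(aj$probs[, "Death"]), 1 - km_at, tolerance = 1e-9)
})

test_that("AJ agrees with the parametric truth on a simulated cohort", {
  mm <- et_preset(n_subjects = 1)$true_model
  cfg <- generator_config(4000, mm, admin_censor_time = 40,
                          random_censor_rate = 0, seed = 14)
  coh <- simulate_cohort(cfg)
  tg <- c(5, 10, 20)
  aj <- aalen_johansen(coh, times = tg)
  truth <- state_occupation(mm, times = tg)
  for (j in seq_along(tg)) for (st in c("Diagnosis", "Thrombosis", "Death")) {
    p <- truth$probs[j, st]
    se <- sqrt(p * (1 - p) / 4000)
    expect_equal(aj$probs[j, st], p, tolerance = 3.5 * se / max(p, 1e-9))
  }
})

test_that("AJ matches the survival package's multistate estimator", {
  coh <- simulate_cohort(prepmf_preset(n_subjects = 400, seed = 17))
  tg <- c(5, 10, 20)
  aj <- aalen_johansen(coh, times = tg)
  long <- to_long(coh)
  # survfit wants one row per sojourn with a factor endpoint
  soj <- long[long$status == 1 | !duplicated(paste(long$subject_id,
                                                   long$from)), ]
  soj <- soj[order(soj$subject_id, soj$tstart, -soj$status), ]
  soj <- soj[!duplicated(paste(soj$subject_id, soj$from)), ]
  ev <- factor(ifelse(soj$status == 1, soj$to, "censor"),
               levels = c("censor", "Thrombosis", "OvertMF", "BlastPhase",
                          "Death"))
  sf <- survival::survfit(
    survival::Surv(tstart, tstop, ev) ~ 1, data = soj,
    id = subject_id, istate = factor(soj$from, levels = c("Diagnosis",
      "Thrombosis", "OvertMF", "BlastPhase", "Death")))
  sm <- summary(sf, times = tg)
  ref <- sm$pstate
  colnames(ref) <- sm$states
  for (st in c("Diagnosis", "Thrombosis", "Death"))
    expect_equal(unname(aj$probs[, st]), unname(ref[, st]),
                 tolerance = 1e-6)
})

test_that("tied cross-subject event times are rejected with advice", {
  coh <- blank_cohort(3)
  coh$death_time[1:2] <- 4
  coh$censor_time[1:2] <- NA
  expect_error(aalen_johansen(coh, times = 5), "jitter")
})
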