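#' Configuration for the synthetic-cohort generator
#'
#' Bundles everything the simulator needs: the number of subjects, the
#' ground-truth [multistate_model()], a covariate generator, the censoring
#' scheme and the seed.  Censoring is the minimum of a fixed
#' administrative horizon and an independent exponential dropout time.
#'
#' @param n_subjects positive integer.
#' @param true_model a [multistate_model()] driving the event process.
#' @param covariate_spec `NULL` (no covariates), a function `n ->
#'   data.frame`, or a parameter list in the shape of
#'   [default_covariate_spec()].
#' @param admin_censor_time administrative censoring horizon, years (> 0).
#' @param random_censor_rate exponential dropout rate per year (>= 0).
#' @param seed integer seed; every draw the generator makes is a pure
#'   function of `(config, seed)`.
#' @return An object of class `"generator_config"`.
#' @seealso [et_preset()], [prepmf_preset()], [simulate_cohort()]
#' @export
generator_config <- function(n_subjects, true_model, covariate_spec = NULL,
                             admin_censor_time = 30, random_censor_rate = 0,
                             seed = 1L) {
  stopifnot(inherits(true_model, "multistate_model"))
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (admin_censor_time <= 0) stop("admin_censor_time must be > 0")
  if (random_censor_rate < 0) stop("random_censor_rate must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), true_model = true_model,
                 covariate_spec = covariate_spec,
                 admin_censor_time = admin_censor_time,
                 random_censor_rate = random_censor_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default baseline-covariate distributions
#'
#' Package defaults for an ET/pre-PMF-like population (the source cohorts'
#' baseline tables are not public, so these are documented package
#' choices): age ~ Normal(60, 15) truncated to \[18, 95\] years; WBC
#' lognormal with median 9 and platelets lognormal with median 700
#' (x 10^9/L); JAK2V617F ~ Bernoulli(0.6); cardiovascular risk factors ~
#' Bernoulli(0.4); prior thrombosis ~ Bernoulli(0.15); sex ~
#' Bernoulli(0.5) F/M; incident thrombosis arterial with probability 0.7.
#'
#' @return A parameter list consumed by [simulate_cohort()].
#' @export
default_covariate_spec <- function() {
  list(age = list(mean = 60, sd = 15, lower = 18, upper = 95),
       wbc = list(meanlog = log(9), sdlog = 0.30),
       plt = list(meanlog = log(700), sdlog = 0.35),
       jak2 = 0.6, cv_risk = 0.4, prior_thrombosis = 0.15,
       p_female = 0.5, p_arterial = 0.7)
}

draw_covariates <- function(spec, n) {
  if (is.null(spec)) return(NULL)
  if (is.function(spec)) return(spec(n))
  age <- stats::qnorm(
    stats::runif(n,
                 stats::pnorm(spec$age$lower, spec$age$mean, spec$age$sd),
                 stats::pnorm(spec$age$upper, spec$age$mean, spec$age$sd)),
    spec$age$mean, spec$age$sd)
  data.frame(
    age = age,
    sex = ifelse(stats::runif(n) < spec$p_female, "F", "M"),
    wbc = stats::rlnorm(n, spec$wbc$meanlog, spec$wbc$sdlog),
    plt = stats::rlnorm(n, spec$plt$meanlog, spec$plt$sdlog),
    jak2 = as.integer(stats::runif(n) < spec$jak2),
    cv_risk = as.integer(stats::runif(n) < spec$cv_risk),
    prior_thrombosis = as.integer(stats::runif(n) < spec$prior_thrombosis),
    stringsAsFactors = FALSE)
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate one disease history
#'
#' Starting in the initial state at t = 0, repeatedly draws a
#' unit-exponential deviate E and solves
#' \eqn{\int_u^t Q_r(w | x)\, dw = E} for the exit time t, where
#' \eqn{Q_r} is the total exit intensity of the current state on the
#' clock-forward scale and u the state-entry time; the destination is then
#' drawn with probability proportional to each exit intensity at t.  The
#' path stops at absorption or at the censoring time, whichever comes
#' first.  For all-exponential exits the inversion is closed-form;
#' otherwise it is solved by bracketed root finding on the cumulative
#' exit intensity.
#'
#' Uses the current RNG stream; see [simulate_cohort()] for seeded,
#' reproducible cohorts.
#'
#' @param model a [multistate_model()].
#' @param covariates named list/one-row data.frame of covariate values
#'   (or `NULL`).
#' @param admin_censor_time,random_censor_rate censoring scheme.
#' @return A one-row wide-format data.frame (without `subject_id`).
#' @export
simulate_path <- function(model, covariates = NULL, admin_censor_time = 30,
                          random_censor_rate = 0) {
  v <- sim_path_times(model, covariates, admin_censor_time,
                      random_censor_rate)
  row <- as.data.frame(as.list(v))
  names(row) <- c(unname(.state_time_cols), "censor_time")
  row
}

# core path simulator; returns c(thrombosis, mf, bp, death, censor) times
# (generic: entered-state times named by the model's states, NA if unvisited)
sim_path_times <- function(model, covariates, admin_censor_time,
                           random_censor_rate) {
  ts <- model$structure
  censor <- admin_censor_time
  if (random_censor_rate > 0)
    censor <- min(censor, stats::rexp(1, random_censor_rate))
  state <- ts$space$states[1]
  u <- 0
  entered <- stats::setNames(rep(NA_real_, length(ts$space$states)),
                             ts$space$states)
  died <- FALSE
  repeat {
    if (state %in% ts$space$absorbing) break
    ex <- exit_edges(ts, state)
    specs <- model$hazards[ex$trans]
    lps <- vapply(specs, lp_factor, numeric(1), x = covariates)
    E <- stats::rexp(1)
    t_exit <- solve_exit_time(specs, lps, u, E)
    if (t_exit > censor) break  # censored in a transient state
    w <- vapply(seq_along(specs), function(j)
      baseline_intensity(specs[[j]], t_exit) * lps[j], numeric(1))
    if (!all(is.finite(w)) || sum(w) <= 0)
      stop("degenerate destination weights at t = ", t_exit)
    dest <- ex$to[sample.int(length(w), 1L, prob = w)]
    entered[dest] <- t_exit
    state <- dest
    u <- t_exit
  }
  died <- any(!is.na(entered[ts$space$absorbing]))
  c(entered[setdiff(names(entered), ts$space$states[1])],
    censor_time = if (died) NA_real_ else censor)
}

# solve sum_k lp_k * (H0_k(t) - H0_k(u)) = E for t > u
solve_exit_time <- function(specs, lps, u, E) {
  fams <- vapply(specs, function(s) s$family, character(1))
  if (all(fams == "exponential")) {
    Q <- sum(vapply(specs, function(s) s$rate, numeric(1)) * lps)
    return(u + E / Q)
  }
  cum <- function(t) {
    v <- sum(vapply(seq_along(specs), function(j)
      lps[j] * (baseline_cumhaz(specs[[j]], t) -
                baseline_cumhaz(specs[[j]], u)), numeric(1)))
    if (!is.finite(v)) stop("non-finite cumulative hazard at t = ", t)
    v
  }
  upper <- u + 1
  while (cum(upper) < E) {
    upper <- u + 2 * (upper - u)
    if (upper - u > 1e6) return(Inf)  # bounded hazard never reaches E
  }
  stats::uniroot(function(t) cum(t) - E, lower = u, upper = upper,
                 tol = 1e-12)$root
}

#' Simulate a cohort of disease histories
#'
#' Draws `n_subjects` covariate profiles and independent paths under the
#' configured ground-truth model and censoring scheme.  Fully reproducible:
#' the same `(config, seed)` yields an identical cohort, and the caller's
#' RNG state is left untouched.  The incident-thrombosis type (arterial vs
#' venous) is drawn at the thrombotic event for subjects who reach it.
#'
#' @param config a [generator_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return A wide-format cohort data.frame (see [cohort-format]) that
#'   validates against the model's transition structure.
#' @examples
#' coh <- simulate_cohort(et_preset(n_subjects = 50))
#' head(coh)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- as.integer(seed %||% config$seed)
  n <- config$n_subjects
  with_seed(seed, {
    covs <- draw_covariates(config$covariate_spec, n)
    covl <- if (is.null(covs)) NULL else as.list(covs)  # list-of-columns view
    tmat <- matrix(NA_real_, n, 5L)
    for (i in seq_len(n)) {
      xi <- if (is.null(covl)) NULL else lapply(covl, `[`, i)
      tmat[i, ] <- tryCatch(
        sim_path_times(config$true_model, xi, config$admin_censor_time,
                       config$random_censor_rate),
        error = function(e) stop("subject ", i, ": ", conditionMessage(e)))
    }
    wide <- data.frame(subject_id = sprintf("s%05d", seq_len(n)),
                       thrombosis_time = tmat[, 1], mf_time = tmat[, 2],
                       bp_time = tmat[, 3], death_time = tmat[, 4],
                       censor_time = tmat[, 5], stringsAsFactors = FALSE)
    if (!is.null(covs)) {
      covs$thrombosis_type <- ifelse(
        is.na(wide$thrombosis_time), "",
        ifelse(stats::runif(n) < arterial_prob(config), "arterial", "venous"))
      wide <- cbind(wide, covs)
    }
    rownames(wide) <- NULL
    wide
  })
}

arterial_prob <- function(config) {
  sp <- config$covariate_spec
  if (is.list(sp) && !is.null(sp$p_arterial)) sp$p_arterial else 0.7
}

#' Calibrate constant competing exit rates to occupancy targets
#'
#' Under constant competing hazards out of the initial state (destinations
#' treated as absorbing), the closed forms
#' \eqn{P_{stay}(h) = e^{-\Lambda h}} and
#' \eqn{P_s(h) = (\lambda_s / \Lambda)(1 - e^{-\Lambda h})} with
#' \eqn{\Lambda = \sum_s \lambda_s} invert exactly: given the event-free
#' probability and per-destination first-transition probabilities at a
#' horizon, the rates are
#' \eqn{\Lambda = -\log(P_{stay})/h},
#' \eqn{\lambda_s = P_s \Lambda / (1 - e^{-\Lambda h})}.
#'
#' @param event_free probability of still being in the initial state at
#'   `horizon`, in (0, 1).
#' @param destinations named numeric vector of first-transition
#'   probabilities by `horizon`, each in (0, 1);
#'   `event_free + sum(destinations)` must not exceed 1.
#' @param horizon years (> 0).
#' @return Named vector of rates per year, with attributes `total` (the
#'   summed exit intensity \eqn{\Lambda}) and `unassigned` (leftover rate
#'   when the targets do not exhaust 1; zero when they do).
#' @examples
#' calibrate_exponential_exits(0.7, c(Death = 0.3), horizon = 10)
#' @export
calibrate_exponential_exits <- function(event_free, destinations, horizon) {
  if (!(event_free > 0 && event_free < 1))
    stop("event_free must be in (0, 1)")
  if (any(destinations <= 0 | destinations >= 1))
    stop("destination targets must be in (0, 1)")
  if (event_free + sum(destinations) > 1 + 1e-12)
    stop("infeasible targets: event_free + destinations exceed 1")
  if (horizon <= 0) stop("horizon must be > 0")
  Lambda <- -log(event_free) / horizon
  rates <- destinations * Lambda / (1 - exp(-Lambda * horizon))
  attr(rates, "total") <- Lambda
  attr(rates, "unassigned") <- Lambda - sum(rates)
  rates
}
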