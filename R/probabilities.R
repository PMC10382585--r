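#' Transition-probability matrices from a parametric model
#'
#' Solves the Kolmogorov forward equations
#' \eqn{dP(s,t)/dt = P(s,t) Q(t)}, \eqn{P(s,s) = I}, by adaptive explicit
#' integration, where \eqn{Q(t)} holds the model's transition intensities
#' off-diagonal and minus the total exit intensity on the diagonal.  In
#' the default progressive structure the (Diagnosis, Thrombosis) entry is
#' the direct transition probability to thrombosis — it can rise and then
#' fall, because thrombosis is itself a transient state.
#'
#' Row sums are monitored; drift beyond 1e-5 from 1 is raised as an error
#' (it signals an integration failure and is never papered over by
#' renormalization).
#'
#' @param model a [multistate_model()] or [msm_fit()].
#' @param s origin time in years (default 0).
#' @param times increasing grid of evaluation times, all `>= s`.
#' @param covariates optional named list/vector of covariate values shared
#'   by all transitions' linear predictors.
#' @param rtol,atol solver tolerances.
#' @return An object of class `"probability_path"`: list with `times`,
#'   `states`, and `P`, an array of dimension
#'   `(length(times), n_states, n_states)` with `P[j, r, s]` the
#'   probability of being in state `s` at `times[j]` given state `r` at
#'   time `s`.
#' @examples
#' ts <- transition_structure()
#' mm <- multistate_model(ts, rep(list(hazard_spec("exponential", 0.03)), 10))
#' pp <- transition_probability(mm, times = c(0, 5, 10))
#' pp$P[3, "Diagnosis", "Death"]
#' @export
transition_probability <- function(model, s = 0, times, covariates = NULL,
                                   rtol = 1e-8, atol = 1e-10) {
  model <- as_multistate_model(model)
  if (is.unsorted(times, strictly = TRUE)) stop("'times' must be strictly increasing")
  if (times[1] < s) stop("all evaluation times must be >= s")
  S <- n_states(model$structure)
  states <- model$structure$space$states
  grid <- unique(c(s, times))
  if (length(grid) == 1L) {
    P <- array(diag(S), dim = c(1L, S, S))
  } else {
    # Weibull baselines with shape < 1 are singular (but integrable) at
    # t = 0; evaluating the intensity at a floored time keeps the solver
    # stable and perturbs the cumulative intensity far below the solver
    # tolerances.
    qfun <- function(t) intensity_matrix(model, max(t, 1e-8), covariates)
    deriv <- function(t, y, parms) {
      P <- matrix(y, S, S)
      list(as.vector(P %*% qfun(t)))
    }
    sol <- deSolve::ode(y = as.vector(diag(S)), times = grid, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("Kolmogorov forward solver failed (istate = ",
           attr(sol, "istate")[1], ")")
    P <- array(sol[, -1, drop = FALSE], dim = c(length(grid), S, S))
  }
  keep <- match(times, grid)
  P <- P[keep, , , drop = FALSE]
  drift <- max(abs(apply(P, c(1, 2), sum) - 1))
  if (drift > 1e-5)
    stop("row-sum drift ", format(drift), " exceeds 1e-5; integration failed")
  dimnames(P) <- list(NULL, states, states)
  structure(list(s = s, times = times, states = states, P = P),
            class = "probability_path")
}

# intensity matrix Q(t) for a single covariate profile
intensity_matrix <- function(model, t, covariates = NULL) {
  S <- n_states(model$structure)
  states <- model$structure$space$states
  Q <- matrix(0, S, S, dimnames = list(states, states))
  ed <- model$structure$edges
  for (k in seq_len(nrow(ed)))
    Q[ed$from[k], ed$to[k]] <- intensity_at(model, k, t, covariates)
  diag(Q) <- -rowSums(Q)
  Q
}

as_multistate_model <- function(model) {
  if (inherits(model, "msm_fit")) model$model
  else if (inherits(model, "multistate_model")) model
  else stop("expected a multistate_model or msm_fit")
}

#' @export
print.probability_path <- function(x, ...) {
  cat("Transition probabilities P(s = ", x$s, ", t) on ",
      length(x$times), " times in [", min(x$times), ", ", max(x$times),
      "] years\n", sep = "")
  cat("Final matrix P(s, ", max(x$times), "):\n", sep = "")
  print(round(x$P[length(x$times), , ], 4))
  invisible(x)
}

#' @export
plot.probability_path <- function(x, from = x$states[1], to = NULL,
                                  xlab = "Years since origin",
                                  ylab = "Transition probability", ...) {
  to <- to %||% setdiff(x$states, from)
  y <- x$P[, from, to, drop = FALSE]
  y <- matrix(y, nrow = length(x$times),
              dimnames = list(NULL, to))
  graphics::matplot(x$times, y, type = "l", lty = 1, lwd = 2,
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("topleft", legend = colnames(y), lty = 1, lwd = 2,
                   col = seq_len(ncol(y)), bty = "n")
  invisible(x)
}

#' State-occupation probabilities from a parametric model
#'
#' Occupation probabilities are the initial distribution propagated by the
#' transition-probability matrix: with all mass in Diagnosis, the
#' Diagnosis entry is the "event-free" probability and the Death entry is
#' the overall probability of having died by each time.
#'
#' @inheritParams transition_probability
#' @param initial initial distribution over states (default: all mass in
#'   the first state); must sum to 1.
#' @return An object of class `"occupation_curve"`: list with `times`,
#'   `states`, and `probs`, a `(length(times), n_states)` matrix whose rows
#'   sum to 1.
#' @examples
#' ts <- transition_structure()
#' mm <- multistate_model(ts, rep(list(hazard_spec("exponential", 0.02)), 10))
#' oc <- state_occupation(mm, times = c(0, 10))
#' oc$probs
#' @export
state_occupation <- function(model, times, covariates = NULL, initial = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  model <- as_multistate_model(model)
  S <- n_states(model$structure)
  initial <- initial %||% c(1, rep(0, S - 1L))
  if (length(initial) != S || abs(sum(initial) - 1) > 1e-8)
    stop("'initial' must be a distribution over the ", S, " states")
  pp <- transition_probability(model, s = 0, times = times,
                               covariates = covariates, rtol = rtol,
                               atol = atol)
  probs <- t(apply(pp$P, 1, function(P) drop(initial %*% P)))
  dimnames(probs) <- list(NULL, pp$states)
  structure(list(times = times, states = pp$states, probs = probs),
            class = "occupation_curve")
}

#' @export
print.occupation_curve <- function(x, ...) {
  cat("State-occupation probabilities on", length(x$times), "times\n")
  show <- unique(round(seq(1, length(x$times), length.out = 7)))
  print(round(cbind(time = x$times[show], x$probs[show, , drop = FALSE]), 4))
  invisible(x)
}

#' @export
plot.occupation_curve <- function(x, xlab = "Years since diagnosis",
                                  ylab = "Occupation probability", ...) {
  graphics::matplot(x$times, x$probs, type = "l", lty = 1, lwd = 2,
                    ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::legend("right", legend = x$states, lty = 1, lwd = 2,
                   col = seq_len(ncol(x$probs)), bty = "n")
  invisible(x)
}

#' Aalen-Johansen estimator of state-occupation probabilities
#'
#' Nonparametric companion to the parametric curves: Nelson-Aalen
#' increments \eqn{dA_{rs}(t) = d_{rs}(t) / Y_r(t)} at each observed
#' transition time, accumulated through the product integral
#' \eqn{\prod (I + dA(u))} applied to the initial distribution.  Curves
#' are right-continuous step functions; a grid query takes the value at
#' the largest event time not exceeding it.
#'
#' @inheritParams validate_cohort
#' @param times evaluation grid (years).
#' @param initial initial distribution (default: all mass in the first
#'   state).
#' @return An object of class `"aalen_johansen"`: list with `times`,
#'   `states`, `probs` (occupation at the grid), `event_times`,
#'   `cumhaz` (long data.frame `time, trans, from, to, cumhaz` of
#'   per-transition Nelson-Aalen estimates).
#' @examples
#' coh <- data.frame(subject_id = c("a", "b", "c"),
#'                   thrombosis_time = c(NA, 2, NA), mf_time = NA,
#'                   bp_time = NA, death_time = c(1, NA, NA),
#'                   censor_time = c(NA, 3, 4))
#' aj <- aalen_johansen(coh, times = 2.5)
#' aj$probs  # 1/3 Diagnosis, 1/3 Thrombosis, 1/3 Death
#' @export
aalen_johansen <- function(cohort, ts = transition_structure(),
                           times = seq(0, 30, by = 0.1), initial = NULL) {
  long <- to_long(cohort, ts)
  S <- n_states(ts)
  states <- ts$space$states
  initial <- initial %||% c(1, rep(0, S - 1L))
  if (length(initial) != S || abs(sum(initial) - 1) > 1e-8)
    stop("'initial' must be a distribution over the ", S, " states")
  # one sojourn per (subject, source state); risk window (tstart, tstop]
  soj <- unique(long[c("subject_id", "from", "tstart", "tstop")])
  ev <- long[long$status == 1L, c("tstop", "trans", "from", "to")]
  ev <- ev[order(ev$tstop), , drop = FALSE]
  if (anyDuplicated(ev$tstop))
    stop("tied event times across subjects; pre-jitter the cohort ",
         "(e.g. by 1e-6 years)")
  p <- initial
  K <- nrow(ts$edges)
  cum <- numeric(K)
  probs_ev <- matrix(NA_real_, nrow(ev), S)
  cumhaz_ev <- matrix(NA_real_, nrow(ev), K)
  for (i in seq_len(nrow(ev))) {
    t <- ev$tstop[i]
    r <- ev$from[i]
    Y <- sum(soj$from == r & soj$tstart < t & t <= soj$tstop)
    if (Y == 0L) stop("empty risk set in state ", r, " at time ", t)
    dA <- matrix(0, S, S, dimnames = list(states, states))
    dA[r, ev$to[i]] <- 1 / Y
    dA[r, r] <- -1 / Y
    p <- drop(p %*% (diag(S) + dA))
    cum[ev$trans[i]] <- cum[ev$trans[i]] + 1 / Y
    probs_ev[i, ] <- p
    cumhaz_ev[i, ] <- cum
  }
  # right-continuous step evaluation on the requested grid
  idx <- findInterval(times, ev$tstop)
  probs <- t(vapply(idx, function(j)
    if (j == 0L) initial else probs_ev[j, ], numeric(S)))
  dimnames(probs) <- list(NULL, states)
  cumhaz <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(time = ev$tstop, trans = k, from = ts$edges$from[k],
               to = ts$edges$to[k], cumhaz = cumhaz_ev[, k])
  }))
  structure(list(times = times, states = states, probs = probs,
                 event_times = ev$tstop, cumhaz = cumhaz),
            class = "aalen_johansen")
}

#' @export
print.aalen_johansen <- function(x, ...) {
  cat("Aalen-Johansen state-occupation estimate,",
      length(x$event_times), "transition events\n")
  show <- unique(round(seq(1, length(x$times), length.out = 7)))
  print(round(cbind(time = x$times[show], x$probs[show, , drop = FALSE]), 4))
  invisible(x)
}

#' @export
plot.aalen_johansen <- function(x, xlab = "Years since diagnosis",
                                ylab = "Occupation probability", ...) {
  graphics::matplot(x$times, x$probs, type = "s", lty = 1, lwd = 2,
                    ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  graphics::legend("right", legend = x$states, lty = 1, lwd = 2,
                   col = seq_len(ncol(x$probs)), bty = "n")
  invisible(x)
}
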