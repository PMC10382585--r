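#' Fit a parametric Markov multistate model by maximum likelihood
#'
#' Estimates one parametric intensity per transition from long-format
#' counting-process data.  All intensities live on the clock-forward scale
#' (time since diagnosis), so delayed entry into downstream transitions is
#' handled by the `(tstart, tstop]` risk windows.  Because no parameters
#' are shared across transitions, the likelihood separates and each
#' transition is maximized on its own by quasi-Newton (BFGS) search on
#' log-transformed positive parameters; standard errors come from the
#' numerical Hessian at the optimum.
#'
#' Transitions with zero observed events are reported as inestimable: the
#' rate is fixed at the documented floor of 1e-10 per year, with no
#' covariance, and flagged in the summary.
#'
#' @param data long-format data, as produced by [to_long()] or
#'   [read_long_csv()].
#' @param structure a [transition_structure()].
#' @param family baseline family for every transition (single string) or a
#'   vector/list named by transition id; one of `"exponential"`,
#'   `"weibull"`, `"gompertz"`.
#' @param covariates optional named list, transition id -> character
#'   vector of covariate column names entering that transition's linear
#'   predictor.
#' @param control list; `maxit` (default 500) and `reltol`
#'   (default 1e-12) passed to [stats::optim()].
#' @return An object of class `"msm_fit"` with components `model` (the
#'   fitted [multistate_model()]), `edges` (per-transition summary),
#'   `details` (per-transition parameter vectors, covariance, diagnostics),
#'   `loglik`, `converged`, and the matched call.  Supports `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `predict`, `simulate` and
#'   `residuals`.
#' @examples
#' cfg <- et_preset(n_subjects = 150)
#' coh <- simulate_cohort(cfg)
#' fit <- msm_fit(to_long(coh), family = "exponential")
#' summary(fit)
#' @seealso [transition_probability()], [state_occupation()],
#'   [cox_transition()]
#' @export
msm_fit <- function(data, structure = transition_structure(),
                    family = "weibull", covariates = NULL,
                    control = list()) {
  stopifnot(inherits(structure, "transition_structure"))
  K <- nrow(structure$edges)
  fam <- resolve_family(family, K)
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  hazards <- vector("list", K)
  details <- vector("list", K)
  for (k in seq_len(K)) {
    rec <- data[data$trans == structure$edges$trans[k], , drop = FALSE]
    covs <- if (!is.null(covariates)) covariates[[as.character(k)]] else NULL
    details[[k]] <- fit_one_edge(rec, fam[k], covs, ctl)
    hazards[[k]] <- details[[k]]$spec
  }
  loglik <- sum(vapply(details, function(d) d$loglik, numeric(1)))
  fit <- structure(list(
    model = multistate_model(structure, hazards),
    edges = cbind(structure$edges,
                  family = fam,
                  n_events = vapply(details, function(d) d$n_events, numeric(1)),
                  person_years = vapply(details, function(d) d$person_time,
                                        numeric(1)),
                  converged = vapply(details, function(d) d$converged,
                                     logical(1)),
                  inestimable = vapply(details, function(d) d$inestimable,
                                       logical(1))),
    details = details,
    loglik = loglik,
    n_records = nrow(data),
    converged = all(vapply(details, function(d)
      d$converged || d$inestimable, logical(1))),
    call = match.call()), class = "msm_fit")
  fit
}

resolve_family <- function(family, K) {
  fams <- c("exponential", "weibull", "gompertz")
  if (length(family) == 1L && is.null(names(family)))
    family <- rep(unlist(family), K)
  family <- unlist(family)
  if (!is.null(names(family))) {
    out <- rep("weibull", K)
    out[as.integer(names(family))] <- family
    family <- out
  }
  if (length(family) != K) stop("'family' must name one baseline per transition")
  vapply(family, function(f) match.arg(f, fams), character(1), USE.NAMES = FALSE)
}

# theta <-> hazard_spec transforms: positivity via log scale
spec_from_theta <- function(family, theta, covs) {
  nb <- length(covs)
  beta <- if (nb) stats::setNames(theta[seq_len(nb) + n_base(family)], covs)
          else numeric(0)
  switch(family,
    exponential = hazard_spec("exponential", rate = exp(theta[1]), beta = beta),
    weibull = hazard_spec("weibull", rate = exp(theta[1]),
                          shape = exp(theta[2]), beta = beta),
    gompertz = hazard_spec("gompertz", rate = exp(theta[1]),
                           shape = theta[2], beta = beta))
}

n_base <- function(family) if (family == "exponential") 1L else 2L

theta_names <- function(family, covs) {
  base <- switch(family, exponential = "log_rate",
                 weibull = c("log_rate", "log_shape"),
                 gompertz = c("log_rate", "shape"))
  c(base, covs)
}

fit_one_edge <- function(rec, family, covs, ctl) {
  n_events <- sum(rec$status == 1L)
  person_time <- if (nrow(rec)) sum(rec$tstop - rec$tstart) else 0
  if (n_events == 0L) {
    # inestimable: rate pinned at the documented floor
    return(list(spec = hazard_spec(family, rate = 1e-10,
                                   shape = if (family == "weibull") 1
                                           else if (family == "gompertz") 0),
                theta = NULL, vcov = NULL, loglik = 0, converged = FALSE,
                inestimable = TRUE, n_events = n_events,
                person_time = person_time))
  }
  covs <- as.character(covs %||% character(0))
  rate0 <- max(n_events / person_time, 1e-8)
  theta0 <- c(log(rate0),
              if (family == "weibull") 0 else if (family == "gompertz") 0,
              rep(0, length(covs)))
  nll <- function(theta) {
    spec <- spec_from_theta(family, theta, covs)
    v <- tryCatch(edge_neg_loglik(spec, rec), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(theta0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  nm <- theta_names(family, covs)
  theta <- stats::setNames(opt$par, nm)
  if (!is.null(vc)) dimnames(vc) <- list(nm, nm)
  list(spec = spec_from_theta(family, opt$par, covs), theta = theta,
       vcov = vc, loglik = -opt$value,
       converged = opt$convergence == 0L && !is.null(vc),
       inestimable = FALSE, n_events = n_events, person_time = person_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msm_fit <- function(x, ...) {
  cat("Parametric Markov multistate model fit\n")
  cat("Log-likelihood:", format(x$loglik), " transitions:",
      nrow(x$edges), "\n\n")
  df <- x$edges
  df$rate <- vapply(x$model$hazards, function(h) h$rate, numeric(1))
  df$shape <- vapply(x$model$hazards, function(h) h$shape %||% NA_real_,
                     numeric(1))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.msm_fit <- function(object, ...) {
  rows <- list()
  for (k in seq_along(object$details)) {
    d <- object$details[[k]]
    e <- object$edges[k, c("trans", "from", "to", "family")]
    if (d$inestimable) {
      rows[[length(rows) + 1L]] <-
        cbind(e, parameter = "log_rate", estimate = NA_real_, se = NA_real_,
              n_events = d$n_events, note = "inestimable (0 events)")
      next
    }
    se <- if (!is.null(d$vcov)) sqrt(pmax(diag(d$vcov), 0)) else
      rep(NA_real_, length(d$theta))
    rows[[length(rows) + 1L]] <-
      cbind(e[rep(1, length(d$theta)), ], parameter = names(d$theta),
            estimate = unname(d$theta), se = unname(se),
            n_events = d$n_events, note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, loglik = object$loglik,
                 converged = object$converged),
            class = "summary.msm_fit")
}

#' @export
print.summary.msm_fit <- function(x, ...) {
  cat("Per-transition parameter estimates (transformed scale):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nTotal log-likelihood:", format(x$loglik),
      if (x$converged) "(converged)" else "(NOT fully converged)", "\n")
  invisible(x)
}

#' @export
coef.msm_fit <- function(object, ...) {
  out <- list()
  for (k in seq_along(object$details)) {
    th <- object$details[[k]]$theta
    if (is.null(th)) next
    names(th) <- paste0("trans", object$edges$trans[k], ".", names(th))
    out[[length(out) + 1L]] <- th
  }
  unlist(out)
}

#' @export
vcov.msm_fit <- function(object, ...) {
  lapply(stats::setNames(object$details, object$edges$trans),
         function(d) d$vcov)
}

#' @export
logLik.msm_fit <- function(object, ...) {
  npar <- sum(vapply(object$details, function(d) length(d$theta), integer(1)))
  structure(object$loglik, df = npar, class = "logLik")
}

#' Predict transition or occupation probabilities from a fitted model
#'
#' @param object an [msm_fit()].
#' @param type `"transition"` for the full probability-matrix path
#'   \eqn{P(s, t)}, `"occupation"` for state-occupation probabilities.
#' @param times increasing time grid (years).
#' @param s origin time for `type = "transition"` (default 0).
#' @param covariates optional named list of covariate values.
#' @param initial initial state distribution for `type = "occupation"`
#'   (default: all mass in the first state).
#' @param ... unused.
#' @return A [transition_probability()] or [state_occupation()] object.
#' @export
predict.msm_fit <- function(object, type = c("occupation", "transition"),
                            times = seq(0, 30, by = 0.1), s = 0,
                            covariates = NULL, initial = NULL, ...) {
  type <- match.arg(type)
  if (type == "transition")
    transition_probability(object$model, s = s, times = times,
                           covariates = covariates)
  else
    state_occupation(object$model, times = times, covariates = covariates,
                     initial = initial)
}

#' Simulate cohorts from a fitted multistate model
#'
#' @param object an [msm_fit()].
#' @param nsim number of cohorts.
#' @param seed integer seed (required for reproducibility).
#' @param n_subjects subjects per cohort.
#' @param admin_censor_time,random_censor_rate censoring scheme, as in
#'   [generator_config()].
#' @param covariate_spec covariate generator, as in [generator_config()]
#'   (default: none).
#' @param ... unused.
#' @return A cohort data.frame, or a list of them when `nsim > 1`.
#' @export
simulate.msm_fit <- function(object, nsim = 1, seed = NULL, n_subjects = 100,
                             admin_censor_time = 30, random_censor_rate = 0,
                             covariate_spec = NULL, ...) {
  if (is.null(seed)) stop("'seed' is required for reproducible simulation")
  cfgs <- lapply(seq_len(nsim), function(i)
    generator_config(n_subjects = n_subjects, true_model = object$model,
                     covariate_spec = covariate_spec,
                     admin_censor_time = admin_censor_time,
                     random_censor_rate = random_censor_rate,
                     seed = seed + i - 1L))
  out <- lapply(cfgs, simulate_cohort)
  if (nsim == 1L) out[[1L]] else out
}

#' Martingale residuals of a fitted multistate model
#'
#' Per long-format record: observed event indicator minus the fitted
#' cumulative intensity over the record's risk window.  Sums to
#' approximately zero per transition at the MLE.
#'
#' @param object an [msm_fit()].
#' @param data the long-format data the model was fitted to.
#' @param ... unused.
#' @return Numeric vector, one residual per row of `data`.
#' @export
residuals.msm_fit <- function(object, data, ...) {
  out <- numeric(nrow(data))
  for (k in seq_along(object$model$hazards)) {
    idx <- which(data$trans == object$model$structure$edges$trans[k])
    if (!length(idx)) next
    spec <- object$model$hazards[[k]]
    rec <- data[idx, , drop = FALSE]
    lp <- rep_len(1, nrow(rec))
    if (length(spec$beta)) {
      X <- as.matrix(rec[names(spec$beta)])
      storage.mode(X) <- "double"
      lp <- exp(drop(X %*% spec$beta))
    }
    out[idx] <- rec$status - lp * (baseline_cumhaz(spec, rec$tstop) -
                                   baseline_cumhaz(spec, rec$tstart))
  }
  out
}
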