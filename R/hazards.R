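#' Parametric transition-intensity specifications
#'
#' Each transition carries an intensity \eqn{q(t | x) = q_0(t) \exp(\beta'x)}
#' on the clock-forward time scale (time since diagnosis), with baseline
#' \eqn{q_0}:
#' \itemize{
#'   \item exponential: \eqn{q_0(t) = \lambda};
#'   \item weibull: \eqn{q_0(t) = \lambda \gamma t^{\gamma - 1}}
#'     (shape \eqn{\gamma = 1} recovers the exponential);
#'   \item gompertz: \eqn{q_0(t) = \lambda e^{\gamma t}}
#'     (\eqn{\gamma = 0} recovers the exponential).
#' }
#'
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`.
#' @param rate baseline rate \eqn{\lambda > 0}, per year.
#' @param shape shape parameter \eqn{\gamma} (ignored for exponential;
#'   must be > 0 for weibull).
#' @param beta named numeric vector of log-hazard-ratio coefficients over
#'   covariates (possibly empty).
#' @return An object of class `"hazard_spec"`.
#' @examples
#' hazard_spec("weibull", rate = 0.05, shape = 1.3)
#' hazard_spec("exponential", rate = 0.02, beta = c(age = 0.03))
#' @export
hazard_spec <- function(family = c("exponential", "weibull", "gompertz"),
                        rate, shape = NULL, beta = numeric(0)) {
  family <- match.arg(family)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a positive finite scalar")
  if (family == "exponential") {
    shape <- NULL
  } else {
    if (is.null(shape)) stop("'shape' is required for family ", family)
    if (family == "weibull" && shape <= 0) stop("weibull shape must be > 0")
  }
  if (length(beta) && is.null(names(beta)))
    stop("'beta' must be a named vector")
  structure(list(family = family, rate = rate, shape = shape,
                 beta = beta), class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat(sprintf("%s hazard: rate = %g", x$family, x$rate))
  if (!is.null(x$shape)) cat(sprintf(", shape = %g", x$shape))
  if (length(x$beta))
    cat("; beta:", paste(names(x$beta), signif(x$beta, 4),
                         sep = " = ", collapse = ", "))
  cat("\n")
  invisible(x)
}

# linear predictor exp(beta'x) for a record/covariate list
lp_factor <- function(spec, x) {
  if (!length(spec$beta)) return(1)
  miss <- setdiff(names(spec$beta), names(x))
  if (length(miss))
    stop("covariate(s) missing from record: ", paste(miss, collapse = ", "))
  exp(sum(spec$beta * as.numeric(x[names(spec$beta)])))
}

# baseline intensity q0(t); vectorized in t
baseline_intensity <- function(spec, t) {
  switch(spec$family,
    exponential = rep_len(spec$rate, length(t)),
    weibull = spec$rate * spec$shape * t^(spec$shape - 1),
    gompertz = spec$rate * exp(spec$shape * t))
}

# baseline cumulative intensity from 0 to t; vectorized in t
baseline_cumhaz <- function(spec, t) {
  switch(spec$family,
    exponential = spec$rate * t,
    weibull = spec$rate * t^spec$shape,
    gompertz = if (spec$shape == 0) spec$rate * t
               else spec$rate * expm1(spec$shape * t) / spec$shape)
}

# invert H0(t) = h for h >= 0; returns Inf if unreachable (bounded cum. hazard)
baseline_cumhaz_inverse <- function(spec, h) {
  switch(spec$family,
    exponential = h / spec$rate,
    weibull = (h / spec$rate)^(1 / spec$shape),
    gompertz = {
      if (spec$shape == 0) h / spec$rate
      else {
        arg <- spec$shape * h / spec$rate
        if (arg <= -1) Inf else log1p(arg) / spec$shape
      }
    })
}
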