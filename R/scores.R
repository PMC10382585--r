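#' IPSET risk scores
#'
#' Point values and category cut-points for the two International
#' Prognostic Scores for Essential Thrombocythemia, declared in a single
#' constants table so they can be audited against the score publications:
#'
#' \tabular{llll}{
#'   score \tab factor \tab threshold \tab points \cr
#'   IPSET-survival \tab age \tab >= 60 years \tab 2 \cr
#'   IPSET-survival \tab WBC \tab >= 11 x 10^9/L \tab 1 \cr
#'   IPSET-survival \tab prior thrombosis \tab present \tab 1 \cr
#'   IPSET-thrombosis \tab age \tab > 60 years \tab 1 \cr
#'   IPSET-thrombosis \tab cardiovascular risk factors \tab present \tab 1 \cr
#'   IPSET-thrombosis \tab prior thrombosis \tab present \tab 2 \cr
#'   IPSET-thrombosis \tab JAK2V617F \tab present \tab 2 \cr
#' }
#'
#' Categories: IPSET-survival low = 0, intermediate = 1-2, high = 3-4
#' points; IPSET-thrombosis low < 2, intermediate = 2, high > 2 points.
#' Note the deliberate difference in age-threshold inclusivity: survival
#' uses age >= 60, thrombosis age > 60, each per its source.  Scores are
#' monotone — adding a risk factor never lowers the points or category.
#'
#' @param profile a named list or one-row data.frame with the fields the
#'   score needs: `age`, `wbc`, `prior_thrombosis` for IPSET-survival;
#'   `age`, `cv_risk`, `prior_thrombosis`, `jak2` for IPSET-thrombosis.
#'   Boolean factors are 0/1 or logical.
#' @return A list with `score`, `points` (integer) and `category`
#'   (`"low"`, `"intermediate"`, `"high"`).
#' @examples
#' ipset_survival(list(age = 65, wbc = 12, prior_thrombosis = 1))
#' ipset_thrombosis(list(age = 50, cv_risk = 0, prior_thrombosis = 0,
#'                       jak2 = 1))
#' @name ipset
NULL

.ipset_constants <- list(
  survival = list(points = c(age_ge60 = 2L, wbc_ge11 = 1L,
                             prior_thrombosis = 1L),
                  cuts = function(p) if (p == 0L) "low"
                         else if (p <= 2L) "intermediate" else "high"),
  thrombosis = list(points = c(age_gt60 = 1L, cv_risk = 1L,
                               prior_thrombosis = 2L, jak2 = 2L),
                    cuts = function(p) if (p < 2L) "low"
                           else if (p == 2L) "intermediate" else "high"))

need_field <- function(profile, field) {
  v <- profile[[field]]
  if (is.null(v) || length(v) != 1L || is.na(v))
    stop("missing field '", field, "' in risk profile")
  v
}

#' @rdname ipset
#' @export
ipset_survival <- function(profile) {
  pts <- .ipset_constants$survival$points
  p <- pts[["age_ge60"]] * (need_field(profile, "age") >= 60) +
       pts[["wbc_ge11"]] * (need_field(profile, "wbc") >= 11) +
       pts[["prior_thrombosis"]] *
         as.integer(as.logical(need_field(profile, "prior_thrombosis")))
  list(score = "IPSET-survival", points = as.integer(p),
       category = .ipset_constants$survival$cuts(as.integer(p)))
}

#' @rdname ipset
#' @export
ipset_thrombosis <- function(profile) {
  pts <- .ipset_constants$thrombosis$points
  p <- pts[["age_gt60"]] * (need_field(profile, "age") > 60) +
       pts[["cv_risk"]] *
         as.integer(as.logical(need_field(profile, "cv_risk"))) +
       pts[["prior_thrombosis"]] *
         as.integer(as.logical(need_field(profile, "prior_thrombosis"))) +
       pts[["jak2"]] * as.integer(as.logical(need_field(profile, "jak2")))
  list(score = "IPSET-thrombosis", points = as.integer(p),
       category = .ipset_constants$thrombosis$cuts(as.integer(p)))
}

#' Annotate a cohort with IPSET risk groups
#'
#' Computes the chosen score for every subject and appends the points,
#' the category, and two dummy covariates — `intermediate` and `high`,
#' with the low-risk group as reference — ready for [cox_transition()].
#'
#' @param cohort wide-format cohort (see [cohort-format]).
#' @param score `"ipset_survival"` or `"ipset_thrombosis"`.
#' @return The cohort with columns `<score>_points`, `<score>_category`,
#'   `intermediate`, `high` appended; group sizes are attached as
#'   attribute `"group_sizes"`.
#' @examples
#' coh <- simulate_cohort(et_preset(n_subjects = 50))
#' table(assign_groups(coh, "ipset_thrombosis")$ipset_thrombosis_category)
#' @export
assign_groups <- function(cohort,
                          score = c("ipset_survival", "ipset_thrombosis")) {
  score <- match.arg(score)
  fn <- if (score == "ipset_survival") ipset_survival else ipset_thrombosis
  res <- lapply(seq_len(nrow(cohort)), function(i)
    tryCatch(fn(cohort[i, , drop = FALSE]),
             error = function(e) stop("subject ", cohort$subject_id[i], ": ",
                                      conditionMessage(e))))
  pts <- vapply(res, function(r) r$points, integer(1))
  cat_ <- vapply(res, function(r) r$category, character(1))
  cohort[[paste0(score, "_points")]] <- pts
  cohort[[paste0(score, "_category")]] <- cat_
  cohort$intermediate <- as.integer(cat_ == "intermediate")
  cohort$high <- as.integer(cat_ == "high")
  attr(cohort, "group_sizes") <- table(factor(cat_, levels = c("low",
    "intermediate", "high")))
  cohort
}
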