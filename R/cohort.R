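#' @title Wide-format disease histories
#'
#' @description A cohort is a data.frame with one row per subject.  Event
#' columns hold the time (in years since diagnosis) at which a state was
#' entered, `NA` when it never was: `thrombosis_time`, `mf_time`,
#' `bp_time`, `death_time`.  Exactly one of `death_time` / `censor_time`
#' ends follow-up: a subject either dies (death time present, censor time
#' `NA`) or is last seen alive at `censor_time`.  Remaining columns are
#' baseline covariates, carried along unchanged.
#'
#' @name cohort-format
NULL

# event columns, in state order after Diagnosis
.state_time_cols <- c(Thrombosis = "thrombosis_time", OvertMF = "mf_time",
                      BlastPhase = "bp_time", Death = "death_time")

.required_cols <- c("subject_id", .state_time_cols, "censor_time")

# times at which each non-initial state was entered, named by state
entered_times <- function(row) {
  tt <- unlist(row[.state_time_cols], use.names = FALSE)
  names(tt) <- names(.state_time_cols)
  tt[!is.na(tt)]
}

# end of observation for one subject row
last_observed <- function(row) {
  if (!is.na(row[["death_time"]])) row[["death_time"]] else row[["censor_time"]]
}

#' Validate disease histories against a transition structure
#'
#' Checks every subject's history for internal consistency: non-negative
#' times, strictly ordered events (ties between distinct states are
#' rejected; pre-jitter by a small epsilon such as 1e-6 years if a data
#' source records simultaneous events), a path along allowed transitions
#' only, death terminating observation, and follow-up covering all events.
#' Violations are collected and returned, never raised.
#'
#' @param cohort a wide-format cohort data.frame (see [cohort-format]).
#' @param ts a [transition_structure()].
#' @return A data.frame with columns `subject_id`, `field`, `rule`; zero
#'   rows when every history is valid.
#' @examples
#' coh <- data.frame(subject_id = "a", thrombosis_time = 2, mf_time = NA,
#'                   bp_time = NA, death_time = 5, censor_time = NA)
#' validate_cohort(coh, transition_structure())  # 0 rows
#' @export
validate_cohort <- function(cohort, ts = transition_structure()) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(.required_cols, names(cohort))
  if (length(miss))
    stop("cohort is missing mandatory columns: ", paste(miss, collapse = ", "))
  ids <- as.character(cohort$subject_id)
  tm <- as.matrix(cohort[, .state_time_cols, drop = FALSE])
  colnames(tm) <- names(.state_time_cols)
  death <- tm[, "Death"]
  cens <- cohort$censor_time
  lo <- ifelse(is.na(death), cens, death)
  out <- list()
  bad <- function(id, field, rule)
    out[[length(out) + 1L]] <<- data.frame(subject_id = id, field = field,
                                           rule = rule)
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)]))
      bad(id, "subject_id", "duplicate subject_id")
  }
  edge_key <- paste(ts$edges$from, ts$edges$to, sep = "->")
  for (i in seq_len(nrow(cohort))) {
    id <- ids[i]
    tt <- tm[i, ]
    tt <- tt[!is.na(tt)]
    if (is.na(lo[i])) {
      bad(id, "censor_time",
          "exactly one of death_time/censor_time must be present")
      next
    }
    if (!is.na(death[i]) && !is.na(cens[i]))
      bad(id, "censor_time",
          "death must terminate observation (censor_time must be empty)")
    if (any(tt < 0) || lo[i] < 0) {
      bad(id, "event times", "all times must be non-negative")
      next
    }
    if (anyDuplicated(tt)) {
      bad(id, "event times",
          "simultaneous events are not allowed (pre-jitter tied times)")
      next
    }
    if (length(tt) && max(tt) > lo[i])
      bad(id, "last observed", "events recorded after end of observation")
    if (!is.na(death[i]) && death[i] != lo[i])
      bad(id, "death_time", "death must terminate observation")
    path <- c("Diagnosis", names(sort(tt)))
    for (k in seq_len(length(path) - 1L)) {
      key <- paste(path[k], path[k + 1L], sep = "->")
      if (!key %in% edge_key)
        bad(id, "path", paste0("transition ", key, " is not an allowed edge"))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(subject_id = character(), field = character(),
                  rule = character())
}

#' Expand wide histories to counting-process (long) format
#'
#' For each sojourn of a subject in a transient state `r` over
#' `[t_entry, t_exit]`, one record is emitted per allowed exit transition
#' of `r`, all sharing `(tstart, tstop)`; `status = 1` only on the edge
#' actually taken (all 0 when the sojourn ends by censoring).  This is the
#' standard long format on which the likelihood, Cox regressions with
#' delayed entry, and descriptive tables operate.
#'
#' @inheritParams validate_cohort
#' @return A data.frame with columns `subject_id`, `trans`, `from`, `to`,
#'   `tstart`, `tstop`, `status`, followed by the cohort's covariate
#'   columns.
#' @examples
#' coh <- data.frame(subject_id = "a", thrombosis_time = 1, mf_time = NA,
#'                   bp_time = NA, death_time = 4, censor_time = NA)
#' to_long(coh)  # 4 diagnosis records + 3 thrombosis records
#' @export
to_long <- function(cohort, ts = transition_structure()) {
  v <- validate_cohort(cohort, ts)
  if (nrow(v) > 0)
    stop("cohort does not validate:\n",
         paste(utils::capture.output(print(v)), collapse = "\n"))
  covar_cols <- setdiff(names(cohort), .required_cols)
  ids <- as.character(cohort$subject_id)
  tm <- as.matrix(cohort[, .state_time_cols, drop = FALSE])
  colnames(tm) <- names(.state_time_cols)
  lo_all <- ifelse(is.na(tm[, "Death"]), cohort$censor_time, tm[, "Death"])
  exits <- lapply(stats::setNames(nm = ts$space$states), exit_edges, ts = ts)
  # accumulate per-sojourn blocks as parallel vectors, not data.frames
  acc <- list(row = list(), trans = list(), from = list(), to = list(),
              tstart = list(), tstop = list(), status = list())
  n_blk <- 0L
  for (i in seq_len(nrow(cohort))) {
    tt <- tm[i, ]
    tt <- sort(tt[!is.na(tt)])
    lo <- lo_all[i]
    path_states <- c("Diagnosis", names(tt))
    path_times <- c(0, unname(tt))
    for (k in seq_along(path_states)) {
      r <- path_states[k]
      if (r %in% ts$space$absorbing) break
      t_entry <- path_times[k]
      if (k < length(path_states)) {
        t_exit <- path_times[k + 1L]
        taken <- path_states[k + 1L]
      } else {
        t_exit <- lo
        taken <- NA_character_
      }
      if (t_exit <= t_entry) next  # zero-length terminal sojourn (censored at entry)
      ex <- exits[[r]]
      m <- nrow(ex)
      n_blk <- n_blk + 1L
      acc$row[[n_blk]] <- rep.int(i, m)
      acc$trans[[n_blk]] <- ex$trans
      acc$from[[n_blk]] <- ex$from
      acc$to[[n_blk]] <- ex$to
      acc$tstart[[n_blk]] <- rep.int(t_entry, m)
      acc$tstop[[n_blk]] <- rep.int(t_exit, m)
      acc$status[[n_blk]] <- as.integer(!is.na(taken) & ex$to == taken)
    }
  }
  row_idx <- unlist(acc$row, use.names = FALSE)
  long <- data.frame(
    subject_id = ids[row_idx],
    trans = unlist(acc$trans, use.names = FALSE),
    from = unlist(acc$from, use.names = FALSE),
    to = unlist(acc$to, use.names = FALSE),
    tstart = unlist(acc$tstart, use.names = FALSE),
    tstop = unlist(acc$tstop, use.names = FALSE),
    status = unlist(acc$status, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (length(covar_cols))
    long <- cbind(long, cohort[row_idx, covar_cols, drop = FALSE],
                  row.names = NULL)
  long
}

# round half away from zero, matching clinical reporting style
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Descriptive per-transition table
#'
#' For each transition: the number of subjects making it, the percentage of
#' subjects that ever entered the source state (rounded half-up to one
#' decimal), and the median and interquartile range of the sojourn time
#' among movers (years).  This reproduces the style of descriptive
#' reporting used for ET and pre-PMF cohorts, e.g. 101/791 subjects
#' (12.7\%) moving from diagnosis to thrombosis.
#'
#' @inheritParams validate_cohort
#' @return A data.frame with one row per transition: `trans`, `from`, `to`,
#'   `n_entered` (source-state entrants), `n_moved`, `percent`,
#'   `median_years`, `q1_years`, `q3_years` (NA when no one moves).
#' @export
transition_count_table <- function(cohort, ts = transition_structure()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) stop("empty cohort")
  long <- to_long(cohort, ts)
  entrants <- vapply(ts$space$states, function(s)
    length(unique(long$subject_id[long$from == s])), integer(1))
  out <- ts$edges
  out$n_entered <- entrants[out$from]
  out$n_moved <- NA_integer_
  out$percent <- NA_real_
  out$median_years <- NA_real_
  out$q1_years <- NA_real_
  out$q3_years <- NA_real_
  for (j in seq_len(nrow(out))) {
    rec <- long[long$trans == out$trans[j] & long$status == 1L, ]
    out$n_moved[j] <- nrow(rec)
    out$percent[j] <- if (out$n_entered[j] > 0)
      round_half_up(100 * nrow(rec) / out$n_entered[j], 1) else NA_real_
    if (nrow(rec) > 0) {
      dur <- rec$tstop - rec$tstart
      qs <- stats::quantile(dur, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      out$q1_years[j] <- qs[1]; out$median_years[j] <- qs[2]
      out$q3_years[j] <- qs[3]
    }
  }
  rownames(out) <- NULL
  out
}
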