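#' Read and write cohort and long-format CSV files
#'
#' The wide cohort dialect has mandatory columns `subject_id,
#' thrombosis_time, mf_time, bp_time, death_time, censor_time` plus the
#' baseline covariates `age, sex, wbc, plt, jak2, cv_risk,
#' prior_thrombosis, thrombosis_type`; an empty cell means the event never
#' happened (`thrombosis_type` is one of `arterial`, `venous`, or empty).
#' Files are UTF-8 with a mandatory header and `.` as decimal separator.
#' The long dialect mirrors the conventional multistate counting-process
#' layout: `subject_id, trans, from, to, tstart, tstop, status` plus
#' covariate columns.  Writing serializes times at full precision so a
#' write/read round trip is lossless.
#'
#' @param path file path.
#' @param cohort,long data.frames in the respective formats.
#' @return `read_cohort_csv` and `read_long_csv` return data.frames;
#'   the writers return `path` invisibly.
#' @name cohort-io
NULL

.covariate_cols <- c("age", "sex", "wbc", "plt", "jak2", "cv_risk",
                     "prior_thrombosis", "thrombosis_type")

#' @rdname cohort-io
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), encoding = "UTF-8")
  miss <- setdiff(.required_cols, names(df))
  if (length(miss))
    stop("cohort CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (col in c(.state_time_cols, "censor_time")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("non-numeric time in column '", col, "' at row(s) ",
             paste(bad, collapse = ", "))
      df[[col]] <- num
    }
  }
  dup <- which(duplicated(df$subject_id))
  if (length(dup))
    stop("duplicate subject_id at row(s) ", paste(dup, collapse = ", "))
  df
}

#' @rdname cohort-io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(format_full_precision(cohort), path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cohort-io
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), encoding = "UTF-8")
  need <- c("subject_id", "trans", "from", "to", "tstart", "tstop", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("tstart", "tstop")) {
    suppressWarnings(num <- as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(num))
    if (length(bad))
      stop("non-numeric time in column '", col, "' at row(s) ",
           paste(bad, collapse = ", "))
    df[[col]] <- num
  }
  bad <- which(df$tstart >= df$tstop)
  if (length(bad))
    stop("tstart >= tstop at row(s) ", paste(bad, collapse = ", "))
  if (!all(df$status %in% c(0L, 1L)))
    stop("status must be 0/1")
  df
}

#' @rdname cohort-io
#' @export
write_long_csv <- function(long, path) {
  utils::write.csv(format_full_precision(long), path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# serialize doubles with 17 significant digits so round trips are exact
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- df[[col]]
      s <- vapply(v, function(x)
        if (is.na(x)) NA_character_ else format(x, digits = 17), character(1))
      df[[col]] <- s
    }
  }
  df
}
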