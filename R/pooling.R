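# Number of analysis intervals a subject contributes: up to and including
# the event interval, or all n_exams when censored.
subject_n_intervals <- function(cohort) {
  s <- cohort$subjects
  ifelse(s$delta == 1, s$event_interval, cohort$config$n_exams)
}

check_event_times <- function(cohort) {
  s <- cohort$subjects
  L <- cohort$config$interval_length
  ev <- s$delta == 1
  bad <- ev & (is.na(s$event_time_in_interval) |
                 s$event_time_in_interval <= 0 |
                 s$event_time_in_interval > L)
  if (any(bad))
    abort_data(sprintf(
      "event_time_in_interval outside (0, %g] for subject(s) %s",
      L, paste(utils::head(s$subject_id[bad], 5), collapse = ", ")))
  invisible(cohort)
}

#' Build the person-period dataset
#'
#' One row per subject per interval entered: an interval is a mini follow-up
#' study with covariates frozen at its opening exam. A subject with an event
#' in interval j contributes exactly j rows (the event row carries the
#' within-interval time-to-event); a censored subject contributes `n_exams`
#' rows, each a full interval. Rows after the event interval are excluded.
#' Age at exam is deterministic: `baseline_age + interval_length * (j - 1)`.
#'
#' @param cohort a `cohort` from [simulate_cohort()] or [read_long_csv()].
#' @return data.frame with columns `subject_id`, `interval_index`,
#'   `interval_start_time`, `age_at_exam`, `sex`, `y`, `time_in_interval`,
#'   `event`.
#' @export
build_person_period <- function(cohort) {
  check_event_times(cohort)
  s <- cohort$subjects
  L <- cohort$config$interval_length
  nper <- subject_n_intervals(cohort)
  idx <- rep(seq_len(nrow(s)), nper)
  j <- sequence(nper)
  terminal <- j == nper[idx] & s$delta[idx] == 1
  data.frame(
    subject_id = s$subject_id[idx],
    interval_index = j,
    interval_start_time = L * (j - 1),
    age_at_exam = s$baseline_age[idx] + L * (j - 1),
    sex = s$sex[idx],
    y = cohort$y[cbind(idx, j)],
    time_in_interval = ifelse(terminal, s$event_time_in_interval[idx], L),
    event = as.integer(terminal)
  )
}

#' Build the counting-process dataset
#'
#' `(start, stop]` records on the cumulative time axis for time-dependent Cox
#' fitting: subject rows are contiguous, `y_current` for the j-th row is the
#' exam-j value, baseline age is carried fixed on every row, and only the
#' last row of an event subject has `event = 1` (with `stop` at the event
#' time).
#'
#' @inheritParams build_person_period
#' @return data.frame with columns `subject_id`, `start`, `stop`, `event`,
#'   `baseline_age`, `sex`, `y_current`.
#' @export
build_counting_process <- function(cohort) {
  check_event_times(cohort)
  s <- cohort$subjects
  L <- cohort$config$interval_length
  nper <- subject_n_intervals(cohort)
  idx <- rep(seq_len(nrow(s)), nper)
  j <- sequence(nper)
  terminal <- j == nper[idx] & s$delta[idx] == 1
  data.frame(
    subject_id = s$subject_id[idx],
    start = L * (j - 1),
    stop = ifelse(terminal, L * (j - 1) + s$event_time_in_interval[idx], L * j),
    event = as.integer(terminal),
    baseline_age = s$baseline_age[idx],
    sex = s$sex[idx],
    y_current = cohort$y[cbind(idx, j)]
  )
}

long_csv_columns <- c("subject_id", "exam_index", "exam_time", "age_at_exam",
                      "sex", "y", "event_in_interval", "time_in_interval",
                      "delta")

#' Export a cohort as long-format CSV
#'
#' One row per subject-exam up to (and including) the event interval, with
#' columns `subject_id, exam_index, exam_time, age_at_exam, sex, y,
#' event_in_interval, time_in_interval, delta` (UTF-8, header row).
#' `event_in_interval` is the row-level event flag; `delta` repeats the
#' subject-level indicator on every row.
#'
#' @inheritParams build_person_period
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  pp <- build_person_period(cohort)
  delta <- cohort$subjects$delta[match(pp$subject_id,
                                       cohort$subjects$subject_id)]
  out <- data.frame(
    subject_id = pp$subject_id,
    exam_index = pp$interval_index,
    exam_time = pp$interval_start_time,
    age_at_exam = pp$age_at_exam,
    sex = pp$sex,
    y = pp$y,
    event_in_interval = pp$event,
    time_in_interval = pp$time_in_interval,
    delta = delta
  )
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format cohort CSV
#'
#' Parses and validates a long-format file with the schema written by
#' [write_cohort_csv()] and reconstructs a `cohort` usable by
#' [build_person_period()], [build_counting_process()] and [fit_method()].
#' Exam times must lie on a common equally spaced grid
#' `interval_length * (exam_index - 1)` shared by all subjects; a subject's
#' rows must stop at the event row. Violations are reported with the
#' offending data row numbers.
#'
#' @param path CSV file path.
#' @return an object of class `cohort` (random effects unknown, `u1`/`u2`
#'   are `NA`; exam values after a subject's event interval are `NA`).
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(long_csv_columns, names(df))
  if (length(missing_cols) > 0)
    abort_data(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) abort_data("no data rows")
  rowno <- seq_len(nrow(df))  # data row numbers for messages

  bad <- !df$sex %in% c(0, 1)
  if (any(bad)) abort_data(sprintf("sex must be 0/1 (rows %s)",
                                   paste(utils::head(rowno[bad], 5), collapse = ", ")))
  bad <- !df$event_in_interval %in% c(0, 1) | !df$delta %in% c(0, 1)
  if (any(bad)) abort_data(sprintf("event_in_interval/delta must be 0/1 (rows %s)",
                                   paste(utils::head(rowno[bad], 5), collapse = ", ")))
  if (any(df$exam_index < 1 | df$exam_index != floor(df$exam_index)))
    abort_data("exam_index must be positive integers")

  key <- paste(df$subject_id, df$exam_index)
  if (anyDuplicated(key) > 0)
    abort_data(sprintf("duplicate (subject_id, exam_index) pairs (rows %s)",
                       paste(utils::head(rowno[duplicated(key)], 5), collapse = ", ")))

  n_exams <- max(df$exam_index)
  # infer the common grid spacing from exam_time vs exam_index
  multi <- df$exam_index > 1
  if (any(multi)) {
    Ls <- df$exam_time[multi] / (df$exam_index[multi] - 1)
    L <- Ls[1]
    if (any(abs(Ls - L) > 1e-8))
      abort_data("exam times are not on a common equally spaced grid; only aligned designs with shared exam times are supported")
  } else {
    L <- 5
  }
  if (any(abs(df$exam_time - L * (df$exam_index - 1)) > 1e-8))
    abort_data("exam_time must equal interval_length * (exam_index - 1)")
  if (any(df$time_in_interval <= 0 | df$time_in_interval > L + 1e-8))
    abort_data(sprintf("time_in_interval must be in (0, %g]", L))

  ord <- order(df$subject_id, df$exam_index)
  df <- df[ord, ]
  rowno <- rowno[ord]
  split_idx <- split(seq_len(nrow(df)), df$subject_id)
  subjects <- lapply(names(split_idx), function(sid) {
    ii <- split_idx[[sid]]
    d <- df[ii, ]
    if (!identical(d$exam_index, seq_len(nrow(d)))) {
      if (any(d$exam_index != seq_along(d$exam_index)))
        abort_data(sprintf("subject %s: exam indices must be 1..k without gaps (rows %s)",
                           sid, paste(utils::head(rowno[ii], 5), collapse = ", ")))
    }
    ev <- which(d$event_in_interval == 1)
    if (length(ev) > 1)
      abort_data(sprintf("subject %s has multiple event rows (rows %s)",
                         sid, paste(rowno[ii][ev], collapse = ", ")))
    if (length(ev) == 1 && ev < nrow(d))
      abort_data(sprintf("subject %s has exam rows after the event row (row %d)",
                         sid, rowno[ii][ev]))
    if (length(ev) == 1 && any(d$delta != 1))
      abort_data(sprintf("subject %s: delta must be 1 on all rows of an event subject", sid))
    if (length(ev) == 0 && any(d$delta != 0))
      abort_data(sprintf("subject %s: delta is 1 but no event row present", sid))
    if (length(ev) == 0 && nrow(d) != n_exams)
      abort_data(sprintf("subject %s is censored but has %d of %d exam rows",
                         sid, nrow(d), n_exams))
    baseline_age <- d$age_at_exam[1]
    if (any(abs(d$age_at_exam - (baseline_age + L * (d$exam_index - 1))) > 1e-6))
      abort_data(sprintf("subject %s: age_at_exam must increase by the interval length between exams", sid))
    if (length(unique(d$sex)) != 1)
      abort_data(sprintf("subject %s: sex must be constant", sid))
    non_term_full <- d$time_in_interval[-nrow(d)]
    if (length(non_term_full) > 0 && any(abs(non_term_full - L) > 1e-8))
      abort_data(sprintf("subject %s: time_in_interval must equal the interval length on non-terminal rows", sid))
    has_event <- length(ev) == 1
    if (!has_event && abs(d$time_in_interval[nrow(d)] - L) > 1e-8)
      abort_data(sprintf("subject %s: censored subjects must have full final intervals", sid))
    list(
      subject_id = sid,
      baseline_age = baseline_age,
      sex = d$sex[1],
      event_interval = if (has_event) ev else NA_integer_,
      event_time_in_interval = if (has_event) d$time_in_interval[ev] else NA_real_,
      total_time = if (has_event) L * (ev - 1) + d$time_in_interval[ev]
                   else L * n_exams,
      delta = as.integer(has_event),
      y = d$y
    )
  })
  n <- length(subjects)
  y <- matrix(NA_real_, n, n_exams)
  for (i in seq_len(n)) {
    yi <- subjects[[i]]$y
    y[i, seq_along(yi)] <- yi
  }
  subj_df <- data.frame(
    subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
    baseline_age = vapply(subjects, `[[`, numeric(1), "baseline_age"),
    sex = vapply(subjects, `[[`, numeric(1), "sex"),
    u1 = NA_real_, u2 = NA_real_,
    event_interval = vapply(subjects, `[[`, integer(1), "event_interval"),
    event_time_in_interval = vapply(subjects, `[[`, numeric(1),
                                    "event_time_in_interval"),
    total_time = vapply(subjects, `[[`, numeric(1), "total_time"),
    delta = vapply(subjects, `[[`, integer(1), "delta")
  )
  cfg <- sim_config(n_subjects = n, n_exams = n_exams, interval_length = L,
                    weibull_scale = 1)
  structure(list(subjects = subj_df, y = y, config = cfg,
                 replicate_id = NA_integer_),
            class = "cohort")
}
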