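#' Read raw log-in event records
#'
#' Parses a delimited text file of time-stamped log-in events (one row per
#' page opening or session start). The delimiter is auto-detected from the
#' file extension (`.csv` vs `.tsv`/`.txt`). Column names are configurable so
#' exports from different logging systems can be read without renaming.
#'
#' @param path Path to a CSV or TSV file.
#' @param user_col,time_col Names of the user-identifier and event-timestamp
#'   columns in the file.
#' @return A tibble with columns `user_id` (character) and `event_time`
#'   (`Date`); one row per event, input order preserved. Timestamps may carry
#'   a time of day in the file; only the calendar date is retained, since the
#'   analysis is at daily resolution.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("user_id,event_time", "A,2014-04-01 10:00:00",
#'              "A,2014-04-01 22:15:00", "B,2014-04-03"), f)
#' read_login_events(f)
#' @export
read_login_events <- function(path, user_col = "user_id",
                              time_col = "event_time") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "engtraj_io_error")
  }
  raw <- read_delim_auto(path)
  for (col in c(user_col, time_col)) {
    if (!col %in% names(raw)) {
      abort(sprintf("Required column `%s` is missing from %s.", col, path),
            class = "engtraj_config_error")
    }
  }
  user_id <- as.character(raw[[user_col]])
  if (nrow(raw) > 0 && any(is.na(user_id) | user_id == "")) {
    bad <- which(is.na(user_id) | user_id == "")
    abort(sprintf("Empty user id at row(s): %s.",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "engtraj_record_error")
  }
  event_time <- parse_event_date(raw[[time_col]])
  if (anyNA(event_time) && nrow(raw) > 0) {
    bad <- which(is.na(event_time))
    abort(sprintf("Unparseable timestamp at row(s): %s.",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "engtraj_record_error")
  }
  tibble::tibble(user_id = user_id, event_time = event_time)
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

parse_event_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXt")) return(as.Date(x))
  x <- as.character(x)
  # date-only or date + time-of-day; date part is all that matters here
  d <- as.Date(substr(trimws(x), 1L, 10L), format = "%Y-%m-%d")
  d
}

#' Read a user enrollment table
#'
#' @param path Path to a CSV/TSV with one row per user.
#' @param user_col,date_col Column names for the user id and enrollment date.
#' @return A tibble with columns `user_id` (character), `enrollment_date`
#'   (`Date`), one row per user.
#' @export
read_enrollment <- function(path, user_col = "user_id",
                            date_col = "enrollment_date") {
  raw <- read_delim_auto(path)
  for (col in c(user_col, date_col)) {
    if (!col %in% names(raw)) {
      abort(sprintf("Required column `%s` is missing from %s.", col, path),
            class = "engtraj_config_error")
    }
  }
  out <- tibble::tibble(user_id = as.character(raw[[user_col]]),
                        enrollment_date = parse_event_date(raw[[date_col]]))
  if (anyDuplicated(out$user_id)) {
    abort("Enrollment table has duplicated user ids.",
          class = "engtraj_record_error")
  }
  out
}

#' Convert log-in events to a daily binary engagement matrix
#'
#' Each user's events are aligned to their enrollment date: day 1 is the
#' enrollment day itself, and cell \eqn{(i, d)} is 1 when user \eqn{i} has at
#' least one event on calendar day `enrollment_date + (d - 1)`. Multiple
#' events on a day collapse to a single 1. Events dated before enrollment or
#' after the horizon are dropped and tallied in the `diagnostics` attribute.
#' Enrolled users with no retained events keep an all-zero row, so the matrix
#' always has one row per enrolled user.
#'
#' @param events A tibble as returned by [read_login_events()].
#' @param enrollment A tibble as returned by [read_enrollment()].
#' @param horizon_days Number of days of follow-up per user (day 1 =
#'   enrollment day). Default 365.
#' @return A tibble with `user_id` plus `day_001` ... `day_365` columns of
#'   0/1 indicators, rows in enrollment-table order, with attribute
#'   `diagnostics`: a list with counts of `dropped_before_enrollment` and
#'   `dropped_after_horizon` events.
#' @examples
#' events <- tibble::tibble(
#'   user_id = c("A", "A", "A"),
#'   event_time = as.Date(c("2014-01-01", "2014-01-01", "2014-01-03"))
#' )
#' enr <- tibble::tibble(user_id = "A", enrollment_date = as.Date("2014-01-01"))
#' m <- binarize_daily(events, enr, horizon_days = 7)
#' sum(engagement_days(m)$n_days) # 2 active days
#' @export
binarize_daily <- function(events, enrollment, horizon_days = 365) {
  horizon_days <- stop_if_not_scalar_count(horizon_days, "horizon_days")
  stopifnot(is.data.frame(events), is.data.frame(enrollment))
  unknown <- setdiff(unique(events$user_id), enrollment$user_id)
  if (length(unknown) > 0) {
    abort(sprintf("Events found for user(s) absent from enrollment: %s.",
                  paste(head(unknown, 5L), collapse = ", ")),
          class = "engtraj_record_error")
  }
  n <- nrow(enrollment)
  values <- matrix(0, nrow = n, ncol = horizon_days)
  dropped_before <- 0L
  dropped_after <- 0L
  if (nrow(events) > 0) {
    enr_date <- enrollment$enrollment_date[match(events$user_id,
                                                 enrollment$user_id)]
    day_idx <- as.integer(events$event_time - enr_date) + 1L
    dropped_before <- sum(day_idx < 1L)
    dropped_after <- sum(day_idx > horizon_days)
    keep <- day_idx >= 1L & day_idx <= horizon_days
    row_idx <- match(events$user_id[keep], enrollment$user_id)
    values[cbind(row_idx, day_idx[keep])] <- 1
  }
  out <- values_to_engagement_tbl(enrollment$user_id, values)
  attr(out, "diagnostics") <- list(
    dropped_before_enrollment = as.integer(dropped_before),
    dropped_after_horizon = as.integer(dropped_after)
  )
  out
}

#' Per-user count of active days
#'
#' @param matrix_tbl An engagement matrix tibble from [binarize_daily()].
#' @return A tibble with `user_id` and `n_days`, the row sum of daily
#'   indicators.
#' @export
engagement_days <- function(matrix_tbl) {
  values <- engagement_values(matrix_tbl)
  tibble::tibble(user_id = as.character(matrix_tbl$user_id),
                 n_days = as.integer(rowSums(values)))
}

#' Aggregate daily indicators into weekly log-in counts
#'
#' Weeks are consecutive 7-day blocks starting at day 1 (the enrollment day),
#' giving 52 complete weeks; day 365 belongs to no complete week and is
#' excluded so all weeks are comparable.
#'
#' @param matrix_tbl An engagement matrix tibble with at least 364 day
#'   columns.
#' @return A tibble with `user_id` plus `week_01` ... `week_52` columns of
#'   integer counts in 0..7.
#' @export
weekly_counts <- function(matrix_tbl) {
  values <- engagement_values(matrix_tbl)
  if (ncol(values) < 364) {
    abort(sprintf(
      "Weekly aggregation needs at least 364 day columns; got %d.",
      ncol(values)), class = "engtraj_argument_error")
  }
  weeks <- vapply(seq_len(52), function(w) {
    cols <- (7L * (w - 1L) + 1L):(7L * w)
    as.integer(rowSums(values[, cols, drop = FALSE]))
  }, integer(nrow(values)))
  weeks <- matrix(weeks, nrow = nrow(values), ncol = 52)
  colnames(weeks) <- sprintf("week_%02d", seq_len(52))
  dplyr::bind_cols(tibble::tibble(user_id = as.character(matrix_tbl$user_id)),
                   tibble::as_tibble(weeks))
}

#' Write / read an engagement matrix as CSV
#'
#' Round-trip persistence for the daily binary matrix: a `user_id` column
#' followed by one column per day. [read_engagement_matrix()] validates that
#' every cell is 0/1 and reports the offending cell otherwise.
#'
#' @param matrix_tbl An engagement matrix tibble.
#' @param path Output CSV path.
#' @return `write_engagement_matrix()` returns `path` invisibly;
#'   `read_engagement_matrix()` returns the matrix tibble.
#' @export
write_engagement_matrix <- function(matrix_tbl, path) {
  values <- engagement_values(matrix_tbl) # validates
  out <- values_to_engagement_tbl(matrix_tbl$user_id, values)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_engagement_matrix
#' @export
read_engagement_matrix <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    user_id = "c", .default = "d"), progress = FALSE, show_col_types = FALSE)
  if (!"user_id" %in% names(raw)) {
    abort("Engagement matrix file must have a `user_id` column.",
          class = "engtraj_format_error")
  }
  day_cols <- grep("^day_\\d+$", names(raw), value = TRUE)
  if (length(day_cols) != ncol(raw) - 1L) {
    abort("Engagement matrix file has non-day data columns.",
          class = "engtraj_format_error")
  }
  values <- as.matrix(raw[, day_cols, drop = FALSE])
  if (nrow(raw) > 0L) assert_binary_matrix(values)
  values_to_engagement_tbl(raw$user_id, values)
}
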