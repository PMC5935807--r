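#' Round half away from zero
#'
#' Decimal rounding that resolves exact ties upward (`0.5 -> 1`), matching how
#' percentages and odds ratios are conventionally printed in clinical tables.
#' Base [round()] uses round-half-to-even, which disagrees on ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, 0.135), 2) # 0.13, 0.14
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by one ulp so values that are exact ties in decimal but sit just
  # below .5 in binary still round up
  z <- abs(x) * scale
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps))
  sign(x) * z / scale
}

# Shared input checks -------------------------------------------------------

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "engtraj_argument_error")
  }
  invisible(as.integer(x))
}

assert_binary_matrix <- function(values, what = "engagement matrix") {
  not_binary <- values != 0 & values != 1
  if (any(not_binary)) {
    bad <- which(not_binary, arr.ind = TRUE)[1, , drop = TRUE]
    abort(sprintf("Non-binary value in %s at row %d, day column %d.",
                  what, bad[[1]], bad[[2]]),
          class = "engtraj_format_error")
  }
  invisible(TRUE)
}

# Extract the numeric day-column matrix from an engagement tibble
# (user_id + day_001..day_D) and validate its shape.
engagement_values <- function(matrix_tbl, check_binary = TRUE) {
  if (!is.data.frame(matrix_tbl) || !"user_id" %in% names(matrix_tbl)) {
    abort("Engagement matrix must be a data frame with a `user_id` column.",
          class = "engtraj_argument_error")
  }
  day_cols <- grep("^day_\\d+$", names(matrix_tbl), value = TRUE)
  if (length(day_cols) == 0L) {
    abort("Engagement matrix has no `day_###` columns.",
          class = "engtraj_argument_error")
  }
  day_cols <- day_cols[order(as.integer(sub("^day_", "", day_cols)))]
  values <- as.matrix(matrix_tbl[, day_cols, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(matrix_tbl$user_id)
  if (check_binary && nrow(values) > 0L) assert_binary_matrix(values)
  values
}

#' Construct engagement tibbles from raw matrices
#'
#' `day_col_names(D)` gives the canonical `day_###` column names;
#' `values_to_engagement_tbl()` binds a `user_id` column to a numeric
#' N x D matrix under those names. Useful for building inputs in examples,
#' simulations and tests.
#'
#' @param D Number of days.
#' @param user_ids Character vector of user ids, one per matrix row.
#' @param values Numeric N x D matrix.
#' @return `day_col_names()`: a character vector; `values_to_engagement_tbl()`:
#'   a tibble with `user_id` plus `day_###` columns.
#' @export
day_col_names <- function(D) sprintf("day_%03d", seq_len(D))

#' @rdname day_col_names
#' @export
values_to_engagement_tbl <- function(user_ids, values) {
  colnames(values) <- day_col_names(ncol(values))
  dplyr::bind_cols(
    tibble::tibble(user_id = as.character(user_ids)),
    tibble::as_tibble(values)
  )
}
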