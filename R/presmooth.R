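#' Presmooth binary daily series into continuous trajectories
#'
#' Each user's 0/1 daily series is smoothed by Nadaraya-Watson kernel
#' regression on the day index with an Epanechnikov kernel,
#' \eqn{K(u) = 0.75 (1 - u^2)} for \eqn{|u| < 1}. Weights are renormalized
#' near the boundaries (no reflection or padding), so the smoothed value is
#' always a convex combination of observed 0/1 values and lies in \[0, 1\].
#' The result is the per-day probability-like engagement intensity that
#' functional PCA consumes.
#'
#' @param matrix_tbl An engagement matrix tibble from [binarize_daily()];
#'   all cells must be 0/1.
#' @param bandwidth_days Kernel half-width in days (>= 1). The default 14
#'   gives roughly two-week resolution, matching the weekly scale at which
#'   engagement patterns are usually described.
#' @return A tibble with `user_id` plus `day_###` columns of smoothed values
#'   in \[0, 1\], with attributes `bandwidth_days` and `grid` (the day grid
#'   mapped to \[0, 1\]).
#' @examples
#' m <- tibble::tibble(user_id = "u1")
#' m[day_col_names(30)] <- as.list(rep(1, 30))
#' s <- presmooth(m, bandwidth_days = 7)
#' all(abs(as.matrix(s[, -1]) - 1) < 1e-12)
#' @export
presmooth <- function(matrix_tbl, bandwidth_days = 14) {
  if (!is.numeric(bandwidth_days) || length(bandwidth_days) != 1L ||
      is.na(bandwidth_days) || bandwidth_days < 1) {
    abort("`bandwidth_days` must be a single number >= 1.",
          class = "engtraj_argument_error")
  }
  values <- engagement_values(matrix_tbl, check_binary = TRUE)
  D <- ncol(values)
  if (D < 2) {
    abort("Presmoothing needs at least 2 days.",
          class = "engtraj_argument_error")
  }
  W <- epanechnikov_weights(D, bandwidth_days)
  smoothed <- values %*% t(W)
  out <- values_to_engagement_tbl(matrix_tbl$user_id, smoothed)
  attr(out, "bandwidth_days") <- bandwidth_days
  attr(out, "grid") <- trajectory_grid(D)
  out
}

# Row-stochastic smoother matrix: row d holds the normalized Epanechnikov
# weights K((d - j) / h) over days j. Rows sum to 1 exactly, so smoothing
# maps [0,1] data into [0,1].
epanechnikov_weights <- function(D, bandwidth_days) {
  d <- seq_len(D)
  u <- outer(d, d, function(a, b) (a - b) / bandwidth_days)
  K <- 0.75 * (1 - u^2)
  K[abs(u) >= 1] <- 0
  K / rowSums(K)
}

#' Map day indices 1..D onto the unit interval
#'
#' @param D Number of days.
#' @return Numeric vector `(d - 1) / (D - 1)` with endpoints 0 and 1; the
#'   common time argument of all functional objects in the package.
#' @export
trajectory_grid <- function(D) {
  stop_if_not_scalar_count(D, "D", min = 2L)
  (seq_len(D) - 1) / (D - 1)
}
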