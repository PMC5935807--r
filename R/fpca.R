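#' Functional principal component analysis of smoothed trajectories
#'
#' Decomposes the sample of smoothed engagement curves into a mean function
#' plus orthonormal eigenfunctions of the sample covariance operator,
#' summarising each user by a small vector of component scores. The
#' trajectories are observed on a complete, shared daily grid, so the
#' covariance operator is discretized directly: with trapezoid quadrature
#' weights \eqn{w}, the eigenproblem of \eqn{W^{1/2} C W^{1/2}} (symmetric)
#' yields eigenvalues \eqn{\lambda_k} and eigenvectors that are rescaled by
#' \eqn{W^{-1/2}} into eigenfunctions with \eqn{\int \phi_k^2 dt = 1}.
#' Scores are trapezoid-rule integrals \eqn{\xi_{ik} = \int (X_i - \mu)
#' \phi_k \, dt}.
#'
#' The number of retained components K is the smallest number whose
#' cumulative eigenvalue fraction reaches `fve_threshold`, capped at
#' `max_components`. Numerically negative eigenvalues from discretization are
#' excluded. Each eigenfunction's sign is fixed so that its largest-magnitude
#' value is positive, making runs reproducible.
#'
#' @param smoothed A smoothed trajectory tibble from [presmooth()] (or any
#'   `user_id` + `day_###` tibble of real values).
#' @param fve_threshold Target fraction of variance explained, in (0, 1].
#'   Default 0.90.
#' @param max_components Upper bound on K. Default 10.
#' @return An object of class `engtraj_fpca`: a list with `grid`, `mean_fn`
#'   (length-D), `eigenfunctions` (K x D), `eigenvalues` (all positive ones),
#'   `n_components` (K), `fve` (cumulative fraction per component),
#'   `scores` (N x K matrix), and `user_ids`.
#' @examples
#' set.seed(1)
#' m <- values_to_engagement_tbl(paste0("u", 1:20),
#'                               matrix(rep(runif(20), each = 30),
#'                                      nrow = 20, byrow = FALSE))
#' fit <- fit_fpca(m)
#' fit$n_components # 1: curves constant in t vary only in level
#' @export
fit_fpca <- function(smoothed, fve_threshold = 0.90, max_components = 10) {
  if (!is.numeric(fve_threshold) || length(fve_threshold) != 1L ||
      is.na(fve_threshold) || fve_threshold <= 0 || fve_threshold > 1) {
    abort("`fve_threshold` must be a single number in (0, 1].",
          class = "engtraj_argument_error")
  }
  max_components <- stop_if_not_scalar_count(max_components, "max_components")
  X <- engagement_values(smoothed, check_binary = FALSE)
  n <- nrow(X)
  D <- ncol(X)
  if (n < 3) {
    abort("FPCA needs at least 3 curves.", class = "engtraj_argument_error")
  }
  grid <- trajectory_grid(D)
  w <- trapezoid_weights(grid)

  mean_fn <- colMeans(X)
  Xc <- sweep(X, 2L, mean_fn)
  C <- crossprod(Xc) / (n - 1)
  if (max(abs(C)) < 1e-14) {
    abort("All curves are identical: covariance is degenerate.",
          class = "engtraj_degenerate_error")
  }

  sw <- sqrt(w)
  A <- C * tcrossprod(sw)          # W^{1/2} C W^{1/2}
  A <- (A + t(A)) / 2              # enforce symmetry against rounding
  eig <- eigen(A, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12 & eig$values > 0
  lambda <- eig$values[pos]
  phi <- t(eig$vectors[, pos, drop = FALSE] / sw)   # rows phi_k on the grid

  # sign convention: largest-|value| element positive
  flip <- apply(phi, 1L, function(v) sign(v[which.max(abs(v))]))
  phi <- phi * flip

  fve <- cumsum(lambda) / sum(lambda)
  K <- which(fve >= fve_threshold - 1e-12)[1]
  if (is.na(K)) K <- length(lambda)
  K <- min(K, max_components)

  structure(
    list(
      grid = grid,
      mean_fn = mean_fn,
      eigenfunctions = phi[seq_len(K), , drop = FALSE],
      eigenvalues = lambda[seq_len(K)],
      all_eigenvalues = lambda,
      n_components = K,
      fve = fve[seq_len(K)],
      fve_threshold = fve_threshold,
      scores = score_curves(Xc, phi[seq_len(K), , drop = FALSE], w),
      user_ids = as.character(smoothed$user_id)
    ),
    class = "engtraj_fpca"
  )
}

trapezoid_weights <- function(grid) {
  D <- length(grid)
  h <- diff(grid)
  w <- numeric(D)
  w[1] <- h[1] / 2
  w[D] <- h[D - 1] / 2
  if (D > 2) w[2:(D - 1)] <- (h[-1] + h[-(D - 1)]) / 2
  w
}

score_curves <- function(Xc, phi, w) {
  S <- Xc %*% (t(phi) * w)
  colnames(S) <- paste0("pc", seq_len(ncol(S)))
  S
}

#' Project trajectories onto a fitted FPCA basis
#'
#' Computes component scores for (possibly new) smoothed curves using the
#' model's mean function and eigenfunctions; used to place held-out users in
#' the score space of a training fit (e.g. inside the prediction-strength
#' calculation).
#'
#' @param model An `engtraj_fpca` object.
#' @param smoothed A smoothed trajectory tibble on the same day grid.
#' @return A tibble with `user_id` and one `pc#` column per retained
#'   component.
#' @export
transform_scores <- function(model, smoothed) {
  stopifnot(inherits(model, "engtraj_fpca"))
  X <- engagement_values(smoothed, check_binary = FALSE)
  if (ncol(X) != length(model$grid)) {
    abort(sprintf("Grid mismatch: model has %d days, data has %d.",
                  length(model$grid), ncol(X)),
          class = "engtraj_argument_error")
  }
  w <- trapezoid_weights(model$grid)
  S <- score_curves(sweep(X, 2L, model$mean_fn), model$eigenfunctions, w)
  dplyr::bind_cols(tibble::tibble(user_id = as.character(smoothed$user_id)),
                   tibble::as_tibble(S))
}

#' @export
print.engtraj_fpca <- function(x, ...) {
  cat(sprintf(
    "Functional PCA: %d curves on %d-day grid\n  %d component(s), FVE %s\n",
    length(x$user_ids), length(x$grid), x$n_components,
    paste(sprintf("%.3f", x$fve), collapse = " ")))
  invisible(x)
}

#' Tidy an FPCA fit
#'
#' @param x An `engtraj_fpca` object.
#' @param ... Unused.
#' @return One row per retained component: eigenvalue, fraction of variance
#'   explained (individual and cumulative).
#' @export
tidy.engtraj_fpca <- function(x, ...) {
  total <- sum(x$all_eigenvalues)
  tibble::tibble(
    component = seq_len(x$n_components),
    eigenvalue = x$eigenvalues,
    pve = x$eigenvalues / total,
    cumulative_fve = x$fve
  )
}

#' @rdname tidy.engtraj_fpca
#' @export
glance.engtraj_fpca <- function(x, ...) {
  tibble::tibble(
    n_curves = length(x$user_ids),
    n_grid = length(x$grid),
    n_components = x$n_components,
    fve = x$fve[x$n_components],
    fve_threshold = x$fve_threshold
  )
}

#' FPCA scores as a tibble
#'
#' @param model An `engtraj_fpca` object.
#' @return A tibble with `user_id` and `pc#` score columns.
#' @export
fpca_scores <- function(model) {
  stopifnot(inherits(model, "engtraj_fpca"))
  dplyr::bind_cols(tibble::tibble(user_id = model$user_ids),
                   tibble::as_tibble(model$scores))
}
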