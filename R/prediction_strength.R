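#' Prediction strength for selecting the number of clusters
#'
#' For each candidate k, the data are randomly halved; both halves are
#' clustered separately (with [clara()]), and the test half is additionally
#' classified by its nearest *training* medoid. For every test cluster with
#' at least two members, the fraction of ordered pairs of its members that
#' the training classification keeps together is computed; the prediction
#' strength of the split is the minimum of these fractions over test
#' clusters. `ps(1) = 1` by construction. The statistic is averaged over
#' `n_splits` random halvings, and the selected k is the largest candidate
#' whose mean prediction strength reaches `threshold` (falling back to 1).
#'
#' A well-supported clustering structure reproduces across halves, giving
#' values near 1; requesting more clusters than the data support fragments
#' clusters inconsistently and drives the minimum fraction down. Values are
#' not guaranteed to decrease monotonically in k.
#'
#' @param scores Points: tibble with optional `user_id` plus numeric score
#'   columns, or a numeric matrix.
#' @param k_max Largest number of clusters to consider (`N >= 2 * k_max`).
#' @param n_splits Number of random half-splits. Default 20.
#' @param threshold Selection cutoff on the mean prediction strength;
#'   values of 0.8-0.9 are customary. Default 0.80.
#' @param seed Integer seed for the split randomization and the CLARA draws.
#' @param ... Passed on to [clara()] (e.g. `n_samples`, `sample_size`).
#' @return An object of class `engtraj_ps`: list with `curve` (tibble of
#'   `k`, `ps_mean`, `ps_sd`), `threshold`, `selected_k`, `n_splits`,
#'   `seed`.
#' @export
prediction_strength <- function(scores, k_max, n_splits = 20,
                                threshold = 0.80, seed = 1L, ...) {
  X <- point_coords(scores)
  n <- nrow(X)
  k_max <- stop_if_not_scalar_count(k_max, "k_max")
  n_splits <- stop_if_not_scalar_count(n_splits, "n_splits")
  if (n < 2 * k_max) {
    abort(sprintf("N = %d is too small for k_max = %d (need N >= 2*k_max).",
                  n, k_max), class = "engtraj_argument_error")
  }
  ps <- matrix(NA_real_, nrow = n_splits, ncol = k_max)
  ps[, 1] <- 1
  with_local_seed(seed, {
    for (s in seq_len(n_splits)) {
      train_idx <- sort(sample.int(n, floor(n / 2)))
      test_idx <- setdiff(seq_len(n), train_idx)
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      if (k_max >= 2) {
        for (k in 2:k_max) {
          ps[s, k] <- ps_one_split(X[train_idx, , drop = FALSE],
                                   X[test_idx, , drop = FALSE],
                                   k, seed = sub_seed + k, ...)
        }
      }
    }
  })
  curve <- tibble::tibble(
    k = seq_len(k_max),
    ps_mean = colMeans(ps),
    ps_sd = apply(ps, 2L, stats::sd)
  )
  ok <- which(curve$ps_mean >= threshold)
  structure(
    list(curve = curve,
         threshold = threshold,
         selected_k = if (length(ok)) max(ok) else 1L,
         n_splits = n_splits,
         seed = seed),
    class = "engtraj_ps"
  )
}

# Prediction strength of one train/test split at a given k.
ps_one_split <- function(train, test, k, seed, ...) {
  fit_train <- clara(train, k, seed = seed, ...)
  fit_test <- clara(test, k, seed = seed + 1L, ...)
  by_train <- assign_to_medoids(test, fit_train$medoids)$labels
  co_assignment_minimum(fit_test$labels, by_train, k)
}

# Minimum over test clusters (size >= 2) of the fraction of ordered member
# pairs that the reference labelling keeps together.
co_assignment_minimum <- function(test_labels, ref_labels, k) {
  fractions <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    members <- which(test_labels == j)
    nj <- length(members)
    if (nj < 2) next
    cnt <- tabulate(ref_labels[members])
    fractions[j] <- sum(cnt * (cnt - 1)) / (nj * (nj - 1))
  }
  if (all(is.na(fractions))) 1 else min(fractions, na.rm = TRUE)
}

#' @export
print.engtraj_ps <- function(x, ...) {
  cat(sprintf(
    "Prediction strength over %d splits (threshold %.2f): selected k = %d\n",
    x$n_splits, x$threshold, x$selected_k))
  print(x$curve)
  invisible(x)
}

#' Tidy a prediction-strength curve
#'
#' @param x An `engtraj_ps` object.
#' @param ... Unused.
#' @return `tidy()`: tibble of `k`, `ps_mean`, `ps_sd`; `glance()`: one row
#'   with `selected_k`, `threshold`, `n_splits`.
#' @export
tidy.engtraj_ps <- function(x, ...) x$curve

#' @rdname tidy.engtraj_ps
#' @export
glance.engtraj_ps <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k, threshold = x$threshold,
                 n_splits = x$n_splits)
}
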