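#' k-medoids clustering by PAM (partitioning around medoids)
#'
#' Deterministic PAM on Euclidean distances. The BUILD phase greedily selects
#' k medoids, each minimizing the incremental total cost; the SWAP phase
#' repeatedly applies the single best (medoid, non-medoid) exchange that
#' strictly decreases the total cost, until no exchange improves it. All ties
#' are broken by the lowest row index, so the result depends only on the
#' input order — no randomness is involved.
#'
#' @param scores A tibble (or data frame) of points: optional `user_id`
#'   column plus numeric coordinate columns (typically FPCA scores from
#'   [fpca_scores()]).
#' @param k Number of clusters, `1 <= k <= N`.
#' @return An object of class `engtraj_clustering`: list with `k`,
#'   `medoid_indices` (row indices), `medoids` (k x p coordinate matrix),
#'   `labels` (integer vector in 1..k), `total_cost` (sum of distances of
#'   points to their assigned medoid), `user_ids`, and `method`.
#' @examples
#' pts <- tibble::tibble(x = c(0, 0, 1, 10, 10, 11),
#'                       y = c(0, 1, 0, 10, 11, 10))
#' fit <- pam(pts, k = 2)
#' fit$total_cost # 4
#' @export
pam <- function(scores, k) {
  X <- point_coords(scores)
  n <- nrow(X)
  k <- stop_if_not_scalar_count(k, "k")
  if (k > n) {
    abort(sprintf("k = %d exceeds the number of points (%d).", k, n),
          class = "engtraj_argument_error")
  }
  dmat <- as.matrix(stats::dist(X))
  med <- pam_core(dmat, k)
  build_clustering(scores, X, med, method = "pam")
}

# BUILD + SWAP on a precomputed distance matrix; returns medoid indices.
pam_core <- function(dmat, k) {
  n <- nrow(dmat)
  # BUILD: start from the most central point, then greedy additions
  med <- unname(which.min(colSums(dmat)))
  dcur <- dmat[, med]
  while (length(med) < k) {
    cand <- setdiff(seq_len(n), med)
    gains <- colSums(pmin(dmat[, cand, drop = FALSE], dcur))
    best <- cand[which.min(gains)]
    med <- c(med, best)
    dcur <- pmin(dcur, dmat[, best])
  }
  # SWAP: steepest descent over single exchanges
  eps <- 1e-12
  repeat {
    med <- sort(med)
    dsub <- dmat[, med, drop = FALSE]
    if (length(med) == 1L) {
      d1 <- dsub[, 1L]
      d2 <- rep(Inf, n)
      nearest <- rep(1L, n)
    } else {
      nearest <- max.col(-dsub, ties.method = "first")
      d1 <- dsub[cbind(seq_len(n), nearest)]
      dtmp <- dsub
      dtmp[cbind(seq_len(n), nearest)] <- Inf
      d2 <- do.call(pmin, as.data.frame(dtmp))
    }
    cost <- sum(d1)
    nonmed <- setdiff(seq_len(n), med)
    if (length(nonmed) == 0L) break
    best_cost <- cost
    best_swap <- NULL
    for (mi in seq_along(med)) {
      base <- ifelse(nearest == mi, d2, d1)
      swap_costs <- colSums(pmin(dmat[, nonmed, drop = FALSE], base))
      j <- which.min(swap_costs)
      if (swap_costs[j] < best_cost - eps) {
        best_cost <- swap_costs[j]
        best_swap <- c(mi, nonmed[j])
      }
    }
    if (is.null(best_swap)) break
    med[best_swap[1L]] <- best_swap[2L]
  }
  sort(med)
}

point_coords <- function(scores) {
  if (is.matrix(scores)) {
    X <- scores
  } else if (is.data.frame(scores)) {
    num <- vapply(scores, is.numeric, logical(1))
    num["user_id" == names(scores)] <- FALSE
    X <- as.matrix(scores[, num, drop = FALSE])
  } else {
    abort("`scores` must be a data frame or matrix of coordinates.",
          class = "engtraj_argument_error")
  }
  if (nrow(X) == 0L || ncol(X) == 0L) {
    abort("`scores` has no points or no numeric coordinate columns.",
          class = "engtraj_argument_error")
  }
  if (!all(is.finite(X))) {
    abort("Point coordinates must all be finite.",
          class = "engtraj_argument_error")
  }
  X
}

point_ids <- function(scores, n) {
  if (is.data.frame(scores) && "user_id" %in% names(scores)) {
    as.character(scores$user_id)
  } else {
    as.character(seq_len(n))
  }
}

build_clustering <- function(scores, X, med_idx, method) {
  assigned <- assign_to_medoids(X, X[med_idx, , drop = FALSE])
  structure(
    list(
      k = length(med_idx),
      medoid_indices = med_idx,
      medoids = X[med_idx, , drop = FALSE],
      labels = assigned$labels,
      total_cost = assigned$total_cost,
      user_ids = point_ids(scores, nrow(X)),
      method = method
    ),
    class = "engtraj_clustering"
  )
}

#' Assign points to their nearest medoid
#'
#' Euclidean nearest-medoid classification; exact distance ties go to the
#' lowest medoid index.
#'
#' @param scores Points (tibble/data frame with numeric columns, or matrix).
#' @param medoids Medoid coordinates (matrix or data frame, same number of
#'   columns as `scores`).
#' @return A list with `labels` (integer vector) and `total_cost` (sum of
#'   distances to assigned medoids).
#' @export
assign_to_medoids <- function(scores, medoids) {
  X <- point_coords(scores)
  M <- if (is.matrix(medoids)) medoids else point_coords(medoids)
  if (nrow(M) == 0L) {
    abort("`medoids` must contain at least one point.",
          class = "engtraj_argument_error")
  }
  if (ncol(M) != ncol(X)) {
    abort("Points and medoids have different dimensions.",
          class = "engtraj_argument_error")
  }
  # exact per-medoid Euclidean distances (same arithmetic as stats::dist,
  # so costs agree bit-for-bit with distance-matrix computations)
  d <- vapply(seq_len(nrow(M)), function(j) {
    sqrt(rowSums(sweep(X, 2L, M[j, ])^2))
  }, numeric(nrow(X)))
  d <- matrix(d, nrow = nrow(X))
  labels <- max.col(-d, ties.method = "first")
  list(labels = labels,
       total_cost = sum(d[cbind(seq_len(nrow(X)), labels)]))
}

#' CLARA: k-medoids for large point sets via subsampling
#'
#' Runs [pam()] on `n_samples` random subsets and keeps the medoid set with
#' the lowest total cost over the *full* data. After the first draw, each
#' subsequent subset is forced to contain the best medoids found so far, per
#' the classic scheme. With `sample_size = N` and `n_samples = 1` the result
#' is identical to `pam()`.
#'
#' @inheritParams pam
#' @param n_samples Number of random subsets to draw. Default 5.
#' @param sample_size Size of each subset; default `min(N, 40 + 2 * k)`.
#' @param seed Integer seed controlling the subset draws.
#' @return An `engtraj_clustering` object (see [pam()]), with full-data
#'   labels and cost.
#' @export
clara <- function(scores, k, n_samples = 5, sample_size = NULL, seed = 1L) {
  X <- point_coords(scores)
  n <- nrow(X)
  k <- stop_if_not_scalar_count(k, "k")
  if (k > n) {
    abort(sprintf("k = %d exceeds the number of points (%d).", k, n),
          class = "engtraj_argument_error")
  }
  n_samples <- stop_if_not_scalar_count(n_samples, "n_samples")
  if (is.null(sample_size)) sample_size <- min(n, 40 + 2 * k)
  sample_size <- stop_if_not_scalar_count(sample_size, "sample_size")
  if (sample_size < k) {
    abort("`sample_size` must be at least k.",
          class = "engtraj_argument_error")
  }
  sample_size <- min(sample_size, n)

  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(n_samples)) {
      if (sample_size == n) {
        sub <- seq_len(n)
      } else if (is.null(best)) {
        sub <- sort(sample.int(n, sample_size))
      } else {
        keep <- best$med_idx
        pool <- setdiff(seq_len(n), keep)
        sub <- sort(c(keep, sample(pool, sample_size - length(keep))))
      }
      dmat <- as.matrix(stats::dist(X[sub, , drop = FALSE]))
      med_local <- pam_core(dmat, k)
      med_idx <- sub[med_local]
      cost <- assign_to_medoids(X, X[med_idx, , drop = FALSE])$total_cost
      if (is.null(best) || cost < best$cost) {
        best <- list(med_idx = med_idx, cost = cost)
      }
    }
  })
  build_clustering(scores, X, best$med_idx, method = "clara")
}

# Evaluate `code` under a temporary RNG state; the caller's stream resumes
# untouched afterwards.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Canonicalize cluster labels by cluster size
#'
#' Re-indexes clusters so that cluster 1 is the largest (descending size;
#' size ties broken by ascending medoid index). Engagement cohorts are
#' typically dominated by early disengagers, so after relabelling cluster 1
#' is the natural reference ("1-week users") for the association models.
#'
#' @param result An `engtraj_clustering` object.
#' @return The same object with clusters re-indexed.
#' @export
relabel_by_size <- function(result) {
  stopifnot(inherits(result, "engtraj_clustering"))
  sizes <- tabulate(result$labels, nbins = result$k)
  ord <- order(-sizes, result$medoid_indices)
  remap <- integer(result$k)
  remap[ord] <- seq_len(result$k)
  result$labels <- remap[result$labels]
  result$medoid_indices <- result$medoid_indices[ord]
  result$medoids <- result$medoids[ord, , drop = FALSE]
  result
}

#' @export
print.engtraj_clustering <- function(x, ...) {
  cat(sprintf("k-medoids clustering (%s): k = %d, N = %d, total cost = %.4g\n",
              x$method, x$k, length(x$labels), x$total_cost))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a clustering result
#'
#' @param x An `engtraj_clustering` object.
#' @param ... Unused.
#' @return `tidy()`: one row per user with `user_id` and `cluster`;
#'   `glance()`: one row with `k`, `n`, `total_cost`, `method`.
#' @export
tidy.engtraj_clustering <- function(x, ...) {
  tibble::tibble(user_id = x$user_ids, cluster = x$labels)
}

#' @rdname tidy.engtraj_clustering
#' @export
glance.engtraj_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels),
                 total_cost = x$total_cost, method = x$method)
}
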