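test_that("pam solves the two-blob fixture optimally", {
  pts <- tibble::tibble(x = c(0, 0, 1, 10, 10, 11),
                        y = c(0, 1, 0, 10, 11, 10))
  fit <- pam(pts, 2)
  expect_equal(fit$total_cost, 4.0)
  expect_equal(sort(unname(fit$medoids[, "x"])), c(0, 10))
  # oracle: exhaustive over all 15 medoid pairs
  expect_equal(fit$total_cost, exhaustive_kmedoids_cost(as.matrix(pts), 2))
})

test_that("pam saturation and 1-D medians behave as expected", {
  pts <- tibble::tibble(x = c(3, 1, 4, 1, 5))
  full <- pam(pts, 5)
  expect_equal(full$total_cost, 0)
  expect_equal(sort(full$medoid_indices), 1:5)
  one <- pam(tibble::tibble(x = c(0, 1, 2)), 1)
  expect_equal(one$medoid_indices, 2L)
  expect_equal(one$total_cost, 2)
  expect_error(pam(pts, 6), class = "engtraj_argument_error")
  expect_error(pam(pts, 0), class = "engtraj_argument_error")
})

test_that("pam implements greedy BUILD plus steepest single-swap descent", {
  # independent oracle: literal restatement of the algorithm with explicit
  # cost recomputation for every candidate swap
  brute_pam <- function(dmat, k) {
    n <- nrow(dmat)
    cost_of <- function(m) {
      sum(do.call(pmin, as.data.frame(dmat[, m, drop = FALSE])))
    }
    med <- unname(which.min(colSums(dmat)))
    dcur <- dmat[, med]
    while (length(med) < k) {
      cand <- setdiff(seq_len(n), med)
      gains <- colSums(pmin(dmat[, cand, drop = FALSE], dcur))
      best <- cand[which.min(gains)]
      med <- c(med, best)
      dcur <- pmin(dcur, dmat[, best])
    }
    repeat {
      med <- sort(med)
      best_c <- cost_of(med)
      best_s <- NULL
      for (mi in seq_along(med)) {
        for (h in setdiff(seq_len(n), med)) {
          m2 <- med
          m2[mi] <- h
          cc <- cost_of(m2)
          if (cc < best_c - 1e-12) {
            best_c <- cc
            best_s <- c(mi, h)
          }
        }
      }
      if (is.null(best_s)) break
      med[best_s[1]] <- best_s[2]
    }
    sort(med)
  }
  set.seed(99)
  n_opt <- 0L
  for (i in 1:40) {
    n <- sample(4:9, 1)
    k <- sample(1:3, 1)
    X <- matrix(rnorm(n * 2), n)
    fit <- pam(tibble::as_tibble(as.data.frame(X)), k)
    expect_identical(as.integer(fit$medoid_indices),
                     as.integer(brute_pam(as.matrix(stats::dist(X)), k)))
    if (fit$total_cost <= exhaustive_kmedoids_cost(X, k) + 1e-9) {
      n_opt <- n_opt + 1L
    }
  }
  # the local search finds the global optimum in most small instances
  expect_gte(n_opt, 30L)
})

test_that("pam agrees with an independent k-medoids implementation", {
  set.seed(17)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 4), ncol = 2),
             matrix(rnorm(60, c(8, 0)), ncol = 2))
  ours <- pam(tibble::as_tibble(as.data.frame(X)), 3)
  ref <- cluster::pam(X, 3)
  # same optimum cost reached (medoid sets may differ only by ties)
  expect_equal(ours$total_cost,
               sum(do.call(pmin,
                           as.data.frame(as.matrix(stats::dist(X))[, ref$id.med]))),
               tolerance = 1e-8)
})

test_that("assignment uses nearest medoid with lowest-index tie-break", {
  med <- matrix(c(0, 10), ncol = 1)
  a <- assign_to_medoids(matrix(c(0, 4, 10, 5), ncol = 1), med)
  expect_equal(a$labels, c(1L, 1L, 2L, 1L)) # 5 is equidistant -> medoid 1
  expect_equal(a$total_cost, 0 + 4 + 0 + 5)
  expect_error(assign_to_medoids(matrix(1), matrix(numeric(0), 0, 1)),
               class = "engtraj_argument_error")
})

test_that("clara reduces to pam on the full sample and tracks it on blobs", {
  pts <- tibble::tibble(x = c(0, 0, 1, 10, 10, 11),
                        y = c(0, 1, 0, 10, 11, 10))
  p <- pam(pts, 2)
  cl <- clara(pts, 2, n_samples = 1, sample_size = 6, seed = 7)
  expect_identical(cl$medoid_indices, p$medoid_indices)
  expect_identical(cl$labels, p$labels)
  expect_identical(cl$total_cost, p$total_cost)

  # subsets with at least two points per blob always recover the fixture
  for (s in 1:5) {
    cls <- clara(pts, 2, n_samples = 3, sample_size = 5, seed = s)
    expect_equal(cls$total_cost, p$total_cost)
  }

  # two tight 1-D clusters of 300 points each: clara within 1% of pam
  set.seed(123)
  big <- tibble::tibble(x = c(rnorm(300, 0, 0.1), rnorm(300, 10, 0.1)))
  pb <- pam(big, 2)
  cb <- clara(big, 2, seed = 11)
  expect_lt(cb$total_cost, pb$total_cost * 1.01)
  expect_error(clara(big, 5, sample_size = 3, seed = 1),
               class = "engtraj_argument_error")
})

test_that("clara is reproducible for a fixed seed and leaves the RNG alone", {
  set.seed(1)
  X <- tibble::tibble(x = rnorm(200), y = rnorm(200))
  before <- .Random.seed
  a <- clara(X, 3, seed = 5)
  expect_identical(.Random.seed, before)
  b <- clara(X, 3, seed = 5)
  expect_identical(a$medoid_indices, b$medoid_indices)
  expect_identical(a$labels, b$labels)
})

test_that("relabel_by_size orders clusters largest-first", {
  res <- structure(list(
    k = 3L,
    medoid_indices = c(5L, 20L, 60L),
    medoids = matrix(1:3, ncol = 1),
    labels = rep(c(1L, 2L, 3L), c(10, 50, 20)),
    total_cost = 1, user_ids = as.character(1:80), method = "pam"
  ), class = "engtraj_clustering")
  rel <- relabel_by_size(res)
  expect_equal(rel$labels, rep(c(3L, 1L, 2L), c(10, 50, 20)))
  expect_equal(rel$medoid_indices, c(20L, 60L, 5L))

  # equal sizes: order by medoid index
  res$labels <- rep(c(2L, 1L, 3L), c(10, 10, 10))
  res$user_ids <- as.character(1:30)
  rel2 <- relabel_by_size(res)
  expect_equal(rel2$medoid_indices, c(5L, 20L, 60L))

  # k = 1 unchanged
  res1 <- res
  res1$k <- 1L
  res1$labels <- rep(1L, 30)
  res1$medoid_indices <- 4L
  res1$medoids <- matrix(1)
  expect_equal(relabel_by_size(res1)$labels, rep(1L, 30))
})

test_that("tidy and glance summarise clustering results", {
  pts <- tibble::tibble(user_id = letters[1:6],
                        x = c(0, 0, 1, 10, 10, 11))
  fit <- pam(pts, 2)
  td <- tidy(fit)
  expect_named(td, c("user_id", "cluster"))
  expect_equal(td$user_id, letters[1:6])
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_equal(gl$n, 6L)
})
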