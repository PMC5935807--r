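# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

# Engagement tibble from a plain 0/1 matrix.
eng_tbl <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("u", seq_len(nrow(values)))
  values_to_engagement_tbl(ids, values)
}

# A single-row engagement tibble with ones at the given days.
one_user_days <- function(on_days, D = 365, id = "u1") {
  v <- matrix(0, 1, D)
  v[1, on_days] <- 1
  eng_tbl(v, id)
}

# Archetype table with strong, persistent between-group differences; used
# where a test needs recoverable cluster structure rather than the
# trial-calibrated defaults.
separable_archetypes <- function() {
  wk <- function(v) c(v, rep(0, 52 - length(v)))
  tibble::tibble(
    archetype = 1:3,
    name = c("brief", "medium", "persistent"),
    proportion = c(0.4, 0.35, 0.25),
    weekly_target = list(wk(1.5), c(rep(3, 10), rep(0, 42)),
                         c(rep(5, 20), rep(2, 32)))
  )
}

# Exhaustive k-medoid optimum by enumerating all C(N, k) medoid sets.
exhaustive_kmedoids_cost <- function(X, k) {
  X <- as.matrix(X)
  dmat <- as.matrix(stats::dist(X))
  sets <- utils::combn(nrow(X), k)
  costs <- apply(sets, 2L, function(m) {
    sum(do.call(pmin, as.data.frame(dmat[, m, drop = FALSE])))
  })
  min(costs)
}

# Curves on a D-grid from a two-component Karhunen-Loeve expansion with
# known orthonormal basis (sqrt(2) sin / cos) and independent normal scores.
kl_two_component <- function(n, D = 101, sd1 = 2, sd2 = 1) {
  t <- (seq_len(D) - 1) / (D - 1)
  phi1 <- sqrt(2) * sin(2 * pi * t)
  phi2 <- sqrt(2) * cos(2 * pi * t)
  xi1 <- rnorm(n, 0, sd1)
  xi2 <- rnorm(n, 0, sd2)
  list(
    curves = eng_tbl(outer(xi1, phi1) + outer(xi2, phi2)),
    phi = rbind(phi1, phi2),
    scores = cbind(xi1, xi2),
    grid = t
  )
}

trapz <- function(y, x) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
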