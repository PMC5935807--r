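test_that("archetype defaults carry the published profiles and proportions", {
  wq <- default_archetypes("webquit")
  expect_equal(wq$proportion, c(0.55, 0.32, 0.13))
  expect_equal(wq$weekly_target[[3]][c(1, 5)], c(3.7, 1.6))
  expect_equal(wq$weekly_target[[3]][10], 0.25)
  sf <- default_archetypes("smokefree")
  expect_equal(sf$proportion, c(0.49, 0.30, 0.21))
  # control-arm short-term users: near zero after week 1
  expect_true(all(sf$weekly_target[[1]][-1] == 0))
  expect_true(all(vapply(wq$weekly_target,
                         function(t) all(t >= 0 & t <= 7), logical(1))))
  expect_error(default_archetypes("other"))
})

test_that("degenerate generator settings are exactly deterministic", {
  arch <- tibble::tibble(
    archetype = 1L, name = "all-week-1", proportion = 1,
    weekly_target = list(c(7, rep(0, 51))))
  eng <- simulate_engagement(20, arch, heterogeneity_sd = 0,
                             week12_spike = 0, seed = 4)
  v <- as.matrix(eng$matrix[, -1])
  expect_true(all(v[, 1:7] == 1))
  expect_true(all(v[, 8:365] == 0))
  expect_true(all(eng$truth$archetype == 1L))
})

test_that("generator means match the configured weekly targets", {
  arch <- default_archetypes("webquit")
  eng <- simulate_engagement(4000, arch, heterogeneity_sd = 0,
                             week12_spike = 0, seed = 9)
  wk <- as.matrix(weekly_counts(eng$matrix)[, -1])
  g3 <- eng$truth$archetype == 3
  # 52-week users' week-1 mean near 3.7 (MC tolerance at ~500 users)
  expect_equal(mean(wk[g3, 1]), 3.7, tolerance = 0.05)
  expect_equal(mean(wk[g3, 5]), 1.6, tolerance = 0.08)
  g1 <- eng$truth$archetype == 1
  expect_equal(mean(wk[g1, 1]), 1.5, tolerance = 0.05)
  expect_true(all(wk[g1, 2:52] == 0))
  # archetype shares near their mixing proportions
  expect_equal(unname(table(eng$truth$archetype)) / 4000,
               c(0.55, 0.32, 0.13), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("the week-12 spike adds the configured bump", {
  arch <- tibble::tibble(
    archetype = 1L, name = "quiet", proportion = 1,
    weekly_target = list(rep(0, 52)))
  eng <- simulate_engagement(3000, arch, heterogeneity_sd = 0,
                             week12_spike = 0.05, seed = 10)
  v <- as.matrix(eng$matrix[, -1])
  wod <- pmin(ceiling(1:365 / 7), 52)
  expect_equal(mean(v[, wod == 12]), 0.05, tolerance = 0.01)
  expect_true(all(v[, wod != 12] == 0))
})

test_that("covariate marginals match their configuration", {
  cov <- simulate_covariates(10000, seed = 20)
  expect_equal(mean(cov$age), 46.4, tolerance = 0.5)
  expect_true(all(cov$age >= 18 & cov$age <= 80))
  expect_equal(mean(cov$male), 0.20, tolerance = 0.02)
  expect_equal(mean(cov$smoked_gt10yrs), 0.80, tolerance = 0.02)
  expect_equal(mean(cov$commitment), 3.99, tolerance = 0.05)

  none_male <- simulate_covariates(
    500, marginals = list(male = 0), seed = 21)
  expect_true(all(none_male$male == 0))
})

test_that("archetype shifts induce the configured covariate-archetype OR", {
  set.seed(22)
  labels <- sample(1:3, 10000, replace = TRUE, prob = c(0.55, 0.32, 0.13))
  cov <- simulate_covariates(
    10000,
    marginals = list(smoked_gt10yrs = 0.8),
    archetype_shift = list(term = "smoked_gt10yrs", archetype = 3L,
                           log_or = log(1.9)),
    labels = labels, seed = 23)
  tab <- table(cov$smoked_gt10yrs, labels == 3)
  realized <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  expect_equal(log(realized), log(1.9), tolerance = 0.25)
  expect_error(
    simulate_covariates(10, marginals = list(male = 0.5),
                        archetype_shift = list(term = "male", archetype = 1L,
                                               log_or = 1), seed = 1),
    class = "engtraj_argument_error")
})

test_that("outcome generation honours intercepts, group ORs and missingness", {
  lab <- rep(1L, 20000)
  out <- simulate_outcome(lab, intercept = qlogis(0.25), group_log_or = 0,
                          missingness = 0, seed = 30)
  expect_equal(mean(out$abstinent), 0.25, tolerance = 0.02)

  out2 <- simulate_outcome(lab, intercept = qlogis(0.25), group_log_or = 0,
                           missingness = 0.124, seed = 31)
  expect_equal(mean(out2$observed), 0.876, tolerance = 0.01)
  expect_true(all(is.na(out2$abstinent[!out2$observed])))

  # group effects on the log-odds scale are recovered by a logistic fit
  set.seed(32)
  lab3 <- sample(1:3, 5000, replace = TRUE, prob = c(0.55, 0.32, 0.13))
  out3 <- simulate_outcome(lab3, intercept = qlogis(0.206),
                           group_log_or = c(0, log(1.57), log(2.24)),
                           missingness = 0, seed = 33)
  d <- dplyr::bind_cols(tibble::tibble(y = out3$abstinent),
                        engtraj:::cluster_indicators(lab3))
  tab <- odds_ratios(fit_logistic(d, "y", c("cluster2", "cluster3")))
  r2 <- tab[tab$term == "cluster2", ]
  r3 <- tab[tab$term == "cluster3", ]
  expect_true(r2$conf_low <= 1.57 & 1.57 <= r2$conf_high)
  expect_true(r3$conf_low <= 2.24 & 2.24 <= r3$conf_high)

  expect_error(simulate_outcome(lab, group_log_or = c(0.5, 1)),
               class = "engtraj_argument_error")
  expect_error(simulate_outcome(rep(5L, 3)),
               class = "engtraj_argument_error")
  expect_error(simulate_outcome(lab, missingness = 1),
               class = "engtraj_argument_error")
})

test_that("a full cohort is reproducible and internally consistent", {
  coh1 <- simulate_cohort("webquit", n_users = 80, seed = 42)
  coh2 <- simulate_cohort("webquit", n_users = 80, seed = 42)
  expect_identical(coh1$matrix, coh2$matrix)
  expect_identical(coh1$outcomes, coh2$outcomes)
  expect_equal(nrow(coh1$matrix), 80L)
  expect_equal(coh1$covariates$user_id, coh1$matrix$user_id)
  expect_equal(coh1$outcomes$user_id, coh1$matrix$user_id)
  expect_true(all(coh1$truth$archetype %in% 1:3))
})

test_that("the pipeline recovers structure from a separable cohort", {
  aris <- vapply(1:5, function(s) {
    eng <- simulate_engagement(400, separable_archetypes(), seed = s)
    fit <- fit_fpca(presmooth(eng$matrix))
    cl <- relabel_by_size(clara(fpca_scores(fit), 3, seed = s))
    mclust::adjustedRandIndex(cl$labels, eng$truth$archetype)
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})
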