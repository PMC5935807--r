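test_that("cluster percentages use half-up rounding to 2 dp", {
  p <- cluster_proportions(rep(1:3, c(682, 399, 159)))
  expect_equal(p$percent, c(55.00, 32.18, 12.82))
  p2 <- cluster_proportions(rep(1:3, c(645, 395, 269)))
  expect_equal(p2$percent, c(49.27, 30.18, 20.55))
  expect_equal(cluster_proportions(rep(1, 7))$percent, 100.00)
  expect_error(cluster_proportions(integer(0)),
               class = "engtraj_argument_error")
})

test_that("round_half_up resolves decimal ties upward", {
  expect_equal(round_half_up(c(0.125, 0.135, -0.125), 2),
               c(0.13, 0.14, -0.13))
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(87.555, 2), 87.56)
})

test_that("abstinence rates reproduce printed worked examples", {
  lab <- rep(1:3, c(562, 370, 149))
  out <- tibble::tibble(abstinent = rep(c(1L, 0L, 1L, 0L, 1L, 0L),
                                        c(116, 446, 100, 270, 51, 98)))
  ab <- abstinence_by_cluster(lab, out)
  expect_equal(ab$rate_percent, c(20.6, 27.0, 34.2))
  expect_equal(ab$abstinent, c(116, 100, 51))
  expect_equal(ab$denominator, c(562, 370, 149))

  lab2 <- rep(1:3, c(562, 349, 252))
  out2 <- tibble::tibble(abstinent = rep(c(1L, 0L, 1L, 0L, 1L, 0L),
                                         c(139, 423, 85, 264, 81, 171)))
  expect_equal(abstinence_by_cluster(lab2, out2)$rate_percent,
               c(24.7, 24.4, 32.1))

  # zero events
  expect_equal(abstinence_by_cluster(
    rep(1L, 5), tibble::tibble(abstinent = rep(0L, 5)))$rate_percent, 0.0)
})

test_that("missing outcomes shift denominators by analysis mode", {
  lab <- rep(1:2, each = 10)
  out <- tibble::tibble(abstinent = c(rep(1L, 4), rep(0L, 4), NA, NA,
                                      rep(1L, 2), rep(0L, 6), NA, NA))
  cc <- abstinence_by_cluster(lab, out, mode = "complete_case")
  expect_equal(cc$denominator, c(8L, 8L))
  expect_equal(cc$rate_percent, c(50.0, 25.0))
  ms <- abstinence_by_cluster(lab, out, mode = "missing_as_smoking")
  expect_equal(ms$denominator, c(10L, 10L))
  expect_equal(ms$rate_percent, c(40.0, 20.0))
})

test_that("retention arithmetic matches the printed rate", {
  expect_equal(retention_rate(2309, 2637), 87.56)
  expect_error(retention_rate(10, 5), class = "engtraj_argument_error")
})

test_that("weekly profiles average within clusters and match the generator", {
  m <- eng_tbl(matrix(1, 4, 365))
  prof <- weekly_profile(m, c(1, 1, 2, 2))
  expect_true(all(prof$mean_logins == 7))
  expect_equal(nrow(prof), 2 * 52)

  arch <- separable_archetypes()
  eng <- simulate_engagement(900, arch, heterogeneity_sd = 0,
                             week12_spike = 0, seed = 6)
  prof2 <- weekly_profile(eng$matrix, eng$truth$archetype)
  for (g in 1:3) {
    got <- prof2$mean_logins[prof2$cluster == g]
    expect_equal(got, arch$weekly_target[[g]], tolerance = 0.12,
                 ignore_attr = TRUE)
  }
  expect_error(weekly_profile(m, 1:3), class = "engtraj_argument_error")
})

test_that("run_pipeline produces a complete, deterministic report", {
  coh <- simulate_cohort("webquit", n_users = 150, seed = 77)
  rep1 <- run_pipeline(coh$matrix, coh$covariates, coh$outcomes,
                       k = 3, n_splits = 4, seed = 5,
                       candidates = c("male", "smoked_gt10yrs", "commitment"))
  expect_s3_class(rep1, "engtraj_report")
  expect_equal(rep1$manifest$k, 3L)
  expect_equal(rep1$manifest$selected_by, "fixed")
  expect_equal(sum(rep1$proportions$n), 150)
  expect_equal(nrow(rep1$labels), 150)
  expect_true(all(c("term", "odds_ratio", "conf_low", "conf_high",
                    "p_value") %in% names(rep1$outcome_table)))
  # forced trajectory indicators present in the outcome model
  expect_true(all(c("cluster2", "cluster3") %in% rep1$outcome_fit$terms))
  # abstinence summary aligned with clustering
  expect_equal(sum(rep1$abstinence$denominator),
               sum(!is.na(coh$outcomes$abstinent)))

  rep2 <- run_pipeline(coh$matrix, coh$covariates, coh$outcomes,
                       k = 3, n_splits = 4, seed = 5,
                       candidates = c("male", "smoked_gt10yrs", "commitment"))
  expect_identical(rep1$labels, rep2$labels)
  expect_identical(rep1$outcome_table, rep2$outcome_table)
  expect_identical(rep1$proportions, rep2$proportions)
})

test_that("run_pipeline with k auto records the prediction-strength curve", {
  eng <- simulate_engagement(240, separable_archetypes(), seed = 3)
  rep <- run_pipeline(eng$matrix, k = "auto", k_max = 4, n_splits = 5,
                      seed = 9)
  expect_s3_class(rep$prediction_strength, "engtraj_ps")
  expect_equal(rep$manifest$selected_by, "prediction_strength")
  expect_equal(rep$manifest$k, rep$prediction_strength$selected_k)
  expect_equal(rep$clustering$k, rep$manifest$k)
})

test_that("plots build without evaluation errors", {
  eng <- simulate_engagement(120, separable_archetypes(), seed = 2)
  prof <- weekly_profile(eng$matrix, eng$truth$archetype)
  p1 <- plot_weekly_profile(prof)
  expect_s3_class(p1, "ggplot")
  fit <- fit_fpca(presmooth(eng$matrix))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  ps <- prediction_strength(fpca_scores(fit), k_max = 3, n_splits = 4,
                            seed = 1)
  expect_s3_class(ggplot2::autoplot(ps), "ggplot")
})
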