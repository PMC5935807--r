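#' Archetype intensity profiles for the two trial arms
#'
#' Weekly expected log-in days (0-7 per week, 52 weeks) for the three
#' engagement archetypes observed in each arm of the smoking-cessation
#' website trial, transcribed from the published cluster descriptions:
#' a short-lived group active only around week 1, an intermediate group
#' tapering over the first month or so, and (in the experimental arm) a
#' persistent group still logging in roughly monthly through week 52.
#' Targets are zero after each archetype's nominal horizon, except the
#' persistent 52-week group, whose "about once a month" rate is 0.25
#' days/week from week 7 onward.
#'
#' @param arm `"webquit"` (experimental, ACT-based site) or `"smokefree"`
#'   (control site). Mixing proportions are the published cluster shares:
#'   0.55/0.32/0.13 and 0.49/0.30/0.21 respectively.
#' @return A tibble with one row per archetype: `archetype` (1-3), `name`,
#'   `proportion`, and `weekly_target` (list-column of 52-vectors).
#' @examples
#' default_archetypes("webquit")$weekly_target[[3]][1:6]
#' @export
default_archetypes <- function(arm = c("webquit", "smokefree")) {
  arm <- match.arg(arm)
  wk <- function(...) {
    v <- c(...)
    stopifnot(length(v) <= 52)
    c(v, rep(0, 52 - length(v)))
  }
  if (arm == "webquit") {
    tibble::tibble(
      archetype = 1:3,
      name = c("1-week users", "5-week users", "52-week users"),
      proportion = c(0.55, 0.32, 0.13),
      weekly_target = list(
        wk(1.5),
        wk(1.8, 0.8, 1 / 3, 1 / 3, 1 / 3),
        c(3.7, 3.3, 2.7, 2.4, 1.6, 1, rep(0.25, 46))
      )
    )
  } else {
    tibble::tibble(
      archetype = 1:3,
      name = c("1-week users", "4-week users", "5-week users"),
      proportion = c(0.49, 0.30, 0.21),
      weekly_target = list(
        wk(0.8),
        wk(1.0, 0.5, 0.5, 0.5),
        wk(1.5, 1.5, 1.0, 0.5, 0.5)
      )
    )
  }
}

#' Simulate daily binary engagement from archetype profiles
#'
#' Each user is assigned an archetype with the given mixing proportions and
#' then logs in independently each day with probability
#' `weekly_target(week) / 7`, scaled by a user-specific log-normal multiplier
#' (mean 1) that induces realistic between-user overdispersion, plus an
#' optional additive probability bump in week 12 emulating the spike
#' triggered by a 12-week assessment invitation. Probabilities are clipped to
#' \[0, 1\] after all adjustments. Day 365 reuses the week-52 rate.
#'
#' @param n_users Number of users.
#' @param archetypes Archetype tibble as from [default_archetypes()].
#' @param heterogeneity_sd `sdlog` of the per-user log-normal multiplier
#'   (`meanlog = -sdlog^2/2` so the multiplier has mean 1). 0 disables
#'   heterogeneity. Default 0.3.
#' @param week12_spike Additional daily log-in probability during week 12.
#'   Default 0.05.
#' @param horizon_days Days of follow-up. Default 365.
#' @param seed Integer seed.
#' @return A list with `matrix` (engagement tibble, `user_id` +
#'   `day_###`), `truth` (tibble `user_id`, `archetype`, `multiplier`).
#' @export
simulate_engagement <- function(n_users, archetypes,
                                heterogeneity_sd = 0.3,
                                week12_spike = 0.05,
                                horizon_days = 365, seed = 1L) {
  n_users <- stop_if_not_scalar_count(n_users, "n_users")
  horizon_days <- stop_if_not_scalar_count(horizon_days, "horizon_days")
  stopifnot(is.data.frame(archetypes),
            all(c("archetype", "proportion", "weekly_target") %in%
                  names(archetypes)))
  props <- archetypes$proportion
  if (abs(sum(props) - 1) > 1e-8) {
    abort("Archetype proportions must sum to 1.",
          class = "engtraj_argument_error")
  }
  if (heterogeneity_sd < 0 || week12_spike < 0 || week12_spike > 1) {
    abort("`heterogeneity_sd` must be >= 0 and `week12_spike` in [0, 1].",
          class = "engtraj_argument_error")
  }
  week_of_day <- pmin(ceiling(seq_len(horizon_days) / 7), 52L)
  daily_base <- vapply(archetypes$weekly_target,
                       function(t) t[week_of_day] / 7,
                       numeric(horizon_days)) # horizon x G
  with_local_seed(seed, {
    labels <- sample.int(nrow(archetypes), n_users, replace = TRUE,
                         prob = props)
    mult <- if (heterogeneity_sd > 0) {
      rlnorm(n_users, meanlog = -heterogeneity_sd^2 / 2,
             sdlog = heterogeneity_sd)
    } else {
      rep(1, n_users)
    }
    p <- t(daily_base[, labels, drop = FALSE]) * mult     # N x D
    p[, week_of_day == 12L] <- p[, week_of_day == 12L] + week12_spike
    p <- pmin(pmax(p, 0), 1)
    values <- matrix(rbinom(length(p), 1L, p), nrow = n_users)
    list(
      matrix = values_to_engagement_tbl(sprintf("u%05d", seq_len(n_users)),
                                        values),
      truth = tibble::tibble(user_id = sprintf("u%05d", seq_len(n_users)),
                             archetype = labels, multiplier = mult)
    )
  })
}

#' Default marginal distributions for baseline covariates
#'
#' Marginals chosen to mirror a middle-aged, majority-female smoking
#' cessation trial population: age normal(46.4, 13.3) truncated to 18-80;
#' 20% male; 79% smoking half a pack or more; 80% smoking for more than 10
#' years; commitment-to-quit score normal(3.99, 0.75); mental-health screen
#' positives of 56% (depression), 33% (anxiety), 48% (panic), 52% (PTSD).
#'
#' @return Named list of marginal parameters accepted by
#'   [simulate_covariates()].
#' @export
default_covariate_marginals <- function() {
  list(
    age = list(mean = 46.4, sd = 13.3, min = 18, max = 80),
    male = 0.20,
    half_pack_or_more = 0.79,
    smoked_gt10yrs = 0.80,
    commitment = list(mean = 3.99, sd = 0.75),
    depression = 0.557,
    anxiety = 0.333,
    panic = 0.477,
    ptsd = 0.524
  )
}

#' Simulate baseline covariates
#'
#' Draws independent covariates matching configurable marginals. An optional
#' `archetype_shift` hook tilts a binary covariate's prevalence by a log
#' odds ratio within selected archetypes, giving a known ground truth for
#' testing membership models; covariates are otherwise independent of
#' everything, so any association a test recovers is the one injected.
#'
#' @param n Number of users.
#' @param marginals Named list as from [default_covariate_marginals()].
#'   Scalar entries are Bernoulli probabilities; list entries with
#'   `mean`/`sd` (and optional `min`/`max` truncation) are (truncated)
#'   normal.
#' @param archetype_shift Optional list with `term` (binary covariate name),
#'   `archetype` (integer vector), `log_or` (shift applied inside those
#'   archetypes); requires `labels`.
#' @param labels True archetype labels (needed only with `archetype_shift`).
#' @param seed Integer seed.
#' @return A tibble of covariates with `user_id`.
#' @export
simulate_covariates <- function(n, marginals = default_covariate_marginals(),
                                archetype_shift = NULL, labels = NULL,
                                seed = 1L) {
  n <- stop_if_not_scalar_count(n, "n")
  out <- tibble::tibble(user_id = sprintf("u%05d", seq_len(n)))
  with_local_seed(seed, {
    for (nm in names(marginals)) {
      m <- marginals[[nm]]
      if (is.list(m)) {
        x <- rnorm(n, m$mean, m$sd)
        if (!is.null(m$min)) {
          # redraw out-of-range values (truncated normal by rejection)
          for (it in 1:50) {
            bad <- x < m$min | x > m$max
            if (!any(bad)) break
            x[bad] <- rnorm(sum(bad), m$mean, m$sd)
          }
          x <- pmin(pmax(x, m$min), m$max)
        }
        out[[nm]] <- x
      } else {
        p <- rep(m, n)
        if (!is.null(archetype_shift) && archetype_shift$term == nm) {
          if (is.null(labels)) {
            abort("`archetype_shift` requires `labels`.",
                  class = "engtraj_argument_error")
          }
          hit <- labels %in% archetype_shift$archetype
          p[hit] <- stats::plogis(stats::qlogis(p[hit]) +
                                    archetype_shift$log_or)
        }
        out[[nm]] <- rbinom(n, 1L, p)
      }
    }
  })
  out
}

#' Simulate the binary outcome from a logistic model
#'
#' The outcome (e.g. 30-day abstinence at 12 months) follows
#' `logit P(Y = 1) = intercept + group effect + covariate effects`, after
#' which a missing-at-random mask at rate `missingness` models follow-up
#' non-response.
#'
#' @param labels Integer archetype/cluster labels (1-based).
#' @param covariates Optional covariate tibble (only needed with
#'   `covariate_effects`).
#' @param intercept Baseline log-odds for group 1 at covariate value 0.
#'   Default `qlogis(0.206)`, a typical short-term-user abstinence rate.
#' @param group_log_or Per-group log odds ratios vs group 1; first entry
#'   must be 0. Default `c(0, log(1.57), log(2.24))`.
#' @param covariate_effects Named numeric vector of per-unit log-OR
#'   covariate effects. Default none.
#' @param missingness Probability an outcome is missing. Default 0.124.
#' @param seed Integer seed.
#' @return A tibble with `user_id` (when available from `covariates`),
#'   `abstinent` (0/1, `NA` when missing) and `observed` (logical).
#' @export
simulate_outcome <- function(labels, covariates = NULL,
                             intercept = stats::qlogis(0.206),
                             group_log_or = c(0, log(1.57), log(2.24)),
                             covariate_effects = NULL,
                             missingness = 0.124, seed = 1L) {
  n <- length(labels)
  if (any(!labels %in% seq_along(group_log_or))) {
    abort("Every label needs an entry in `group_log_or`.",
          class = "engtraj_argument_error")
  }
  if (group_log_or[1] != 0) {
    abort("`group_log_or[1]` is the reference and must be 0.",
          class = "engtraj_argument_error")
  }
  if (missingness < 0 || missingness >= 1) {
    abort("`missingness` must be in [0, 1).",
          class = "engtraj_argument_error")
  }
  eta <- intercept + group_log_or[labels]
  if (!is.null(covariate_effects) && length(covariate_effects)) {
    stopifnot(is.data.frame(covariates),
              all(names(covariate_effects) %in% names(covariates)))
    X <- as.matrix(covariates[, names(covariate_effects), drop = FALSE])
    eta <- eta + drop(X %*% covariate_effects)
  }
  with_local_seed(seed, {
    y <- rbinom(n, 1L, stats::plogis(eta))
    observed <- runif(n) >= missingness
    tibble::tibble(
      user_id = if (!is.null(covariates) && "user_id" %in% names(covariates))
        covariates$user_id else sprintf("u%05d", seq_len(n)),
      abstinent = ifelse(observed, y, NA_integer_),
      observed = observed
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Bundles [simulate_engagement()], [simulate_covariates()] and
#' [simulate_outcome()] with consistent seeding into the full input set the
#' pipeline expects: a daily engagement matrix, baseline covariates, a
#' partially missing binary outcome, and the true archetype labels.
#'
#' @param arm `"webquit"` or `"smokefree"`.
#' @param n_users Cohort size. Default 1240 (the experimental-arm size).
#' @param seed Integer seed; sub-seeds for the three generators are derived
#'   from it.
#' @param ... Passed to [simulate_engagement()] (e.g. `heterogeneity_sd`,
#'   `week12_spike`).
#' @param outcome_args Optional list of overrides for [simulate_outcome()].
#' @param covariate_args Optional list of overrides for
#'   [simulate_covariates()].
#' @return An object of class `engtraj_cohort`: list with `matrix`,
#'   `covariates`, `outcomes`, `truth`, `arm`, `seed`.
#' @examples
#' coh <- simulate_cohort("webquit", n_users = 50, seed = 7)
#' table(coh$truth$archetype)
#' @export
simulate_cohort <- function(arm = c("webquit", "smokefree"), n_users = 1240,
                            seed = 1L, ..., outcome_args = list(),
                            covariate_args = list()) {
  arm <- match.arg(arm)
  archetypes <- default_archetypes(arm)
  eng <- simulate_engagement(n_users, archetypes, seed = seed, ...)
  cov_tbl <- do.call(simulate_covariates, c(
    list(n = n_users, labels = eng$truth$archetype, seed = seed + 1000L),
    covariate_args))
  out_tbl <- do.call(simulate_outcome, c(
    list(labels = eng$truth$archetype, covariates = cov_tbl,
         seed = seed + 2000L),
    outcome_args))
  structure(
    list(matrix = eng$matrix, covariates = cov_tbl, outcomes = out_tbl,
         truth = eng$truth, archetypes = archetypes, arm = arm, seed = seed),
    class = "engtraj_cohort"
  )
}

#' @export
print.engtraj_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d users x %d days (seed %d)\n",
              x$arm, nrow(x$matrix), ncol(x$matrix) - 1L, x$seed))
  cat("archetype counts:",
      paste(tabulate(x$truth$archetype, nrow(x$archetypes)), collapse = ", "),
      "\n")
  invisible(x)
}
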