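#' Cluster sizes and percentages
#'
#' @param labels Integer or factor cluster labels.
#' @return A tibble with `cluster`, `n`, `percent` (share of all users,
#'   rounded half-up to 2 decimal places, as printed in trial reports).
#' @examples
#' cluster_proportions(rep(1:3, c(682, 399, 159)))
#' @export
cluster_proportions <- function(labels) {
  if (length(labels) == 0) {
    abort("`labels` must be nonempty.", class = "engtraj_argument_error")
  }
  tibble::as_tibble(table(cluster = labels)) |>
    dplyr::rename(n = "n") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / length(labels), 2))
}

#' Mean weekly log-in profile per cluster
#'
#' The per-cluster average of the weekly log-in counts — the numbers behind
#' the weekly trajectory figure for each engagement group.
#'
#' @param matrix_tbl Daily engagement matrix tibble.
#' @param labels Cluster labels aligned to matrix rows.
#' @return A tibble in long format: `cluster`, `week` (1-52),
#'   `mean_logins` (0-7).
#' @export
weekly_profile <- function(matrix_tbl, labels) {
  if (length(labels) != nrow(matrix_tbl)) {
    abort("`labels` must have one entry per matrix row.",
          class = "engtraj_argument_error")
  }
  wk <- weekly_counts(matrix_tbl)
  wk$cluster <- labels
  out <- wk |>
    dplyr::select(-"user_id") |>
    tidyr::pivot_longer(-"cluster", names_to = "week",
                        values_to = "logins") |>
    dplyr::mutate(week = as.integer(sub("week_", "", .data$week))) |>
    dplyr::group_by(.data$cluster, .data$week) |>
    dplyr::summarise(mean_logins = mean(.data$logins), .groups = "drop")
  out
}

#' Abstinence rates by cluster
#'
#' Tabulates the binary outcome within each trajectory cluster. In
#' `"complete_case"` mode the denominator is the number of users with an
#' observed outcome (responders); in `"missing_as_smoking"` mode every user
#' counts and missing outcomes are treated as not abstinent, the
#' conservative convention of cessation trials.
#'
#' @param labels Cluster labels.
#' @param outcomes Tibble with `abstinent` (0/1, `NA` = missing); row-aligned
#'   with `labels`.
#' @param mode `"complete_case"` (default) or `"missing_as_smoking"`.
#' @return A tibble with `cluster`, `abstinent` (count), `denominator`,
#'   `rate_percent` (rounded half-up to 1 dp).
#' @examples
#' lab <- rep(1:3, c(562, 370, 149))
#' out <- tibble::tibble(abstinent = rep(c(1, 0, 1, 0, 1, 0),
#'                                       c(116, 446, 100, 270, 51, 98)))
#' abstinence_by_cluster(lab, out) # 20.6 / 27.0 / 34.2
#' @export
abstinence_by_cluster <- function(labels, outcomes,
                                  mode = c("complete_case",
                                           "missing_as_smoking")) {
  mode <- match.arg(mode)
  if (length(labels) != nrow(outcomes)) {
    abort("`labels` and `outcomes` must be aligned.",
          class = "engtraj_argument_error")
  }
  y <- outcomes$abstinent
  d <- tibble::tibble(cluster = labels, abstinent = y)
  if (mode == "complete_case") {
    d <- d[!is.na(d$abstinent), , drop = FALSE]
  } else {
    d$abstinent[is.na(d$abstinent)] <- 0L
  }
  d |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(abstinent = sum(.data$abstinent),
                     denominator = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rate_percent = round_half_up(
      100 * .data$abstinent / .data$denominator, 1))
}

#' Overall follow-up retention rate
#'
#' @param n_observed Users with an observed outcome.
#' @param n_total Enrolled users.
#' @return Percentage retained, rounded half-up to 2 decimal places.
#' @examples
#' retention_rate(2309, 2637) # 87.56
#' @export
retention_rate <- function(n_observed, n_total) {
  if (n_total <= 0 || n_observed < 0 || n_observed > n_total) {
    abort("Need 0 <= n_observed <= n_total with n_total > 0.",
          class = "engtraj_argument_error")
  }
  round_half_up(100 * n_observed / n_total, 2)
}

#' Run the full engagement-trajectory pipeline
#'
#' Orchestrates the analysis end to end on in-memory inputs: presmooth the
#' daily matrix, fit FPCA, select the number of clusters by prediction
#' strength (unless `k` is fixed), cluster with CLARA, canonicalize labels
#' by cluster size, and produce the standard summaries and association
#' models. Identical inputs, configuration and seed give identical output.
#'
#' @param matrix_tbl Daily engagement matrix tibble ([binarize_daily()]).
#' @param covariates Optional baseline covariate tibble (with `user_id`).
#' @param outcomes Optional outcome tibble (`abstinent`, `NA` = missing),
#'   row-aligned with `matrix_tbl`.
#' @param k Number of clusters, or `"auto"` (default) to select by
#'   prediction strength.
#' @param k_max Largest k considered when `k = "auto"`. Default 6.
#' @param bandwidth_days Presmoothing bandwidth. Default 14.
#' @param fve_threshold FPCA fraction-of-variance cutoff. Default 0.90.
#' @param ps_threshold Prediction-strength selection threshold. Default 0.8.
#' @param n_splits Prediction-strength splits. Default 20.
#' @param candidates Covariate names considered for stepwise adjustment of
#'   the outcome model and screened for the membership model. Default: all
#'   non-`user_id` covariate columns.
#' @param outcome_mode Denominator convention for rates, see
#'   [abstinence_by_cluster()].
#' @param seed Integer seed covering every random element.
#' @return An object of class `engtraj_report`: list with `smoothed`,
#'   `fpca`, `prediction_strength` (NULL when k fixed), `clustering`,
#'   `labels` (tibble), `proportions`, `weekly_profile`, plus — when
#'   outcomes/covariates are given — `abstinence`, `outcome_fit`,
#'   `outcome_table`, `stepwise_trace`, `membership_fit`,
#'   `membership_table`, `screen`, and a `manifest` echoing the
#'   configuration.
#' @export
run_pipeline <- function(matrix_tbl, covariates = NULL, outcomes = NULL,
                         k = "auto", k_max = 6, bandwidth_days = 14,
                         fve_threshold = 0.90, ps_threshold = 0.80,
                         n_splits = 20, candidates = NULL,
                         outcome_mode = "complete_case", seed = 1L) {
  smoothed <- presmooth(matrix_tbl, bandwidth_days = bandwidth_days)
  fpca <- fit_fpca(smoothed, fve_threshold = fve_threshold)
  scores <- fpca_scores(fpca)

  ps <- NULL
  if (identical(k, "auto")) {
    ps <- prediction_strength(scores, k_max = k_max, n_splits = n_splits,
                              threshold = ps_threshold, seed = seed)
    k <- ps$selected_k
  }
  k <- stop_if_not_scalar_count(k, "k")
  clus <- relabel_by_size(clara(scores, k, seed = seed + 1L))
  labels <- tidy(clus)

  report <- list(
    smoothed = smoothed,
    fpca = fpca,
    prediction_strength = ps,
    clustering = clus,
    labels = labels,
    proportions = cluster_proportions(clus$labels),
    weekly_profile = weekly_profile(matrix_tbl, clus$labels)
  )

  if (!is.null(outcomes)) {
    report$abstinence <- abstinence_by_cluster(clus$labels, outcomes,
                                               mode = outcome_mode)
    if (!is.null(covariates)) {
      if (is.null(candidates)) {
        candidates <- setdiff(names(covariates), "user_id")
      }
      d <- dplyr::bind_cols(
        tibble::tibble(abstinent = outcomes$abstinent),
        cluster_indicators(clus$labels),
        covariates[, candidates, drop = FALSE]
      )
      if (outcome_mode == "missing_as_smoking") {
        d$abstinent[is.na(d$abstinent)] <- 0L
      }
      forced <- setdiff(names(cluster_indicators(clus$labels)), character())
      sw <- stepwise_aic(d, "abstinent", forced = forced,
                         candidates = candidates)
      report$outcome_fit <- sw$fit
      report$stepwise_trace <- sw$trace
      report$outcome_table <- odds_ratios(sw$fit)

      scr <- univariate_screen(covariates, clus$labels, candidates)
      report$screen <- scr
      pool <- scr$term[scr$keep]
      if (clus$k >= 2 && length(pool) > 0) {
        msw <- stepwise_multinomial(covariates, clus$labels, pool)
        report$membership_fit <- msw
        report$membership_table <- odds_ratios(msw)
      }
    }
  }

  report$manifest <- list(
    n_users = nrow(matrix_tbl), k = k,
    selected_by = if (is.null(ps)) "fixed" else "prediction_strength",
    bandwidth_days = bandwidth_days, fve_threshold = fve_threshold,
    fpca_components = fpca$n_components, ps_threshold = ps_threshold,
    n_splits = n_splits, outcome_mode = outcome_mode, seed = seed,
    package_version = as.character(utils::packageVersion("engtraj"))
  )
  structure(report, class = "engtraj_report")
}

# 0/1 indicator columns for clusters 2..k (cluster 1 = reference)
cluster_indicators <- function(labels) {
  ks <- sort(unique(labels))
  out <- tibble::as_tibble(
    setNames(lapply(ks[-1], function(g) as.integer(labels == g)),
             paste0("cluster", ks[-1])))
  out
}

# Stepwise AIC over multinomial membership models (forward/backward from the
# screened pool), mirroring stepwise_aic() but with nnet::multinom fits.
stepwise_multinomial <- function(covariates, labels, pool) {
  y <- factor(labels)
  df <- covariates[, pool, drop = FALSE]
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  yk <- y[keep]
  aic_of <- function(terms) {
    f <- terms_formula(".cluster", terms)
    d <- df[, terms, drop = FALSE]
    d$.cluster <- yk
    fit <- nnet::multinom(f, data = d, trace = FALSE, maxit = 500L,
                          reltol = 1e-12)
    fit$AIC %||% AIC(fit)
  }
  current <- character()
  current_aic <- aic_of(character())
  repeat {
    moves <- dplyr::bind_rows(
      if (length(setdiff(pool, current))) {
        tibble::tibble(action = "add", term = setdiff(pool, current))
      },
      if (length(current)) tibble::tibble(action = "drop", term = current)
    )
    if (nrow(moves) == 0) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      trial <- if (moves$action[i] == "add") c(current, moves$term[i]) else
        setdiff(current, moves$term[i])
      tryCatch(aic_of(trial), error = function(e) NA_real_)
    }, numeric(1))
    moves <- moves[!is.na(moves$aic), , drop = FALSE]
    if (nrow(moves) == 0) break
    moves <- moves[order(moves$aic, match(moves$action, c("drop", "add")),
                         moves$term), , drop = FALSE]
    if (moves$aic[1] >= current_aic - 1e-8) break
    current <- if (moves$action[1] == "add") c(current, moves$term[1]) else
      setdiff(current, moves$term[1])
    current_aic <- moves$aic[1]
  }
  fit_multinomial(covariates[keep, , drop = FALSE], yk, sort(current))
}

#' @export
print.engtraj_report <- function(x, ...) {
  cat("Engagement-trajectory pipeline report\n")
  cat(sprintf("  users: %d, k = %d (%s)\n", x$manifest$n_users,
              x$manifest$k, x$manifest$selected_by))
  print(x$proportions)
  if (!is.null(x$abstinence)) {
    cat("abstinence by cluster:\n")
    print(x$abstinence)
  }
  invisible(x)
}
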