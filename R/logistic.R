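#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit of a binary outcome on a set of terms,
#' via iteratively reweighted least squares ([stats::glm()] with a tight
#' convergence tolerance), restricted to complete cases. Standard errors come
#' from the inverse observed information. Perfect separation and
#' rank-deficient designs are turned into explicit errors rather than
#' silently unstable estimates.
#'
#' @param data A data frame with the outcome and all model terms.
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param terms Character vector of predictor column names; may be empty for
#'   an intercept-only model.
#' @return An object of class `engtraj_logit`: list with `fit` (the glm),
#'   `outcome`, `terms`, `n` (complete cases used), `loglik`, `aic`.
#' @examples
#' d <- expand_2x2(a = 116, b = 446, c = 100, d = 270)
#' fit <- fit_logistic(d, "event", "exposed")
#' exp(coef(fit$fit)[["exposed"]]) # 1.424
#' @export
fit_logistic <- function(data, outcome, terms = character()) {
  data <- prepare_model_frame(data, outcome, terms, binary_outcome = TRUE)
  if (nrow(data) < length(terms) + 1L) {
    abort("Too few complete cases for the number of model terms.",
          class = "engtraj_argument_error")
  }
  f <- terms_formula(outcome, terms)
  check_full_rank(f, data)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = data, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 50L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated && any(abs(coef(fit)) > 10)) {
    abort("Perfect or quasi-perfect separation: coefficients diverge.",
          class = "engtraj_separation_error")
  }
  new_engtraj_logit(fit, outcome, terms)
}

new_engtraj_logit <- function(fit, outcome, terms) {
  structure(
    list(fit = fit, outcome = outcome, terms = terms,
         n = stats::nobs(fit), loglik = as.numeric(logLik(fit)),
         aic = AIC(fit)),
    class = "engtraj_logit"
  )
}

prepare_model_frame <- function(data, outcome, terms, binary_outcome = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(outcome, terms), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Column(s) not found in data: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "engtraj_config_error")
  }
  data <- data[, c(outcome, terms), drop = FALSE]
  data <- data[complete.cases(data), , drop = FALSE]
  y <- data[[outcome]]
  if (binary_outcome) {
    if (is.logical(y)) y <- as.integer(y)
    if (!all(y %in% c(0, 1))) {
      abort(sprintf("Outcome `%s` must be binary 0/1.", outcome),
            class = "engtraj_argument_error")
    }
    data[[outcome]] <- y
  }
  data
}

terms_formula <- function(outcome, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(sprintf("`%s`", terms),
                                                collapse = " + ")
  as.formula(sprintf("`%s` ~ %s", outcome, rhs))
}

check_full_rank <- function(f, data) {
  mm <- model.matrix(f, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1L):ncol(mm)]]
    abort(sprintf("Design is rank deficient; collinear term(s): %s.",
                  paste(dropped, collapse = ", ")),
          class = "engtraj_rank_error")
  }
  invisible(TRUE)
}

#' Odds-ratio table from a fitted model
#'
#' Exponentiates coefficients and Wald limits
#' \eqn{\exp(\beta \pm z_{0.975} SE)}; two-sided p-values from the
#' standard-normal Wald z. The intercept is reported on the same scale but is
#' an odds, not an odds ratio.
#'
#' @param fit An `engtraj_logit` or `engtraj_multinom` object.
#' @param conf_level Confidence level for the Wald interval. Default 0.95.
#' @return A tibble with `term`, `estimate` (beta), `std_error`,
#'   `odds_ratio`, `conf_low`, `conf_high`, `p_value` (plus `cluster` for
#'   multinomial fits).
#' @export
odds_ratios <- function(fit, conf_level = 0.95) {
  UseMethod("odds_ratios")
}

#' @export
odds_ratios.engtraj_logit <- function(fit, conf_level = 0.95) {
  beta <- coef(fit$fit)
  se <- sqrt(diag(vcov(fit$fit)))
  wald_or_table(names(beta), beta, se, conf_level)
}

wald_or_table <- function(term, beta, se, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = term,
    estimate = unname(beta),
    std_error = unname(se),
    odds_ratio = exp(unname(beta)),
    conf_low = exp(unname(beta) - z * unname(se)),
    conf_high = exp(unname(beta) + z * unname(se)),
    p_value = 2 * pnorm(-abs(unname(beta) / unname(se)))
  )
}

#' @export
print.engtraj_logit <- function(x, ...) {
  cat(sprintf("Logistic fit: %s ~ %s\n  n = %d, logLik = %.3f, AIC = %.3f\n",
              x$outcome,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$n, x$loglik, x$aic))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x An `engtraj_logit` object.
#' @param ... Unused.
#' @return `tidy()`: the odds-ratio table (see [odds_ratios()]); `glance()`:
#'   one row with `n`, `loglik`, `aic`, `df`.
#' @export
tidy.engtraj_logit <- function(x, ...) odds_ratios(x)

#' @rdname tidy.engtraj_logit
#' @export
glance.engtraj_logit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, aic = x$aic,
                 df = length(coef(x$fit)))
}

#' Odds ratio and Woolf confidence interval from a 2x2 table
#'
#' Closed-form cross-product odds ratio, the textbook oracle against which
#' the one-covariate logistic MLE can be checked exactly. Cell convention:
#' `a` = reference-group events, `b` = reference-group non-events, `c` =
#' exposed-group events, `d` = exposed-group non-events, so
#' `OR = (c * b) / (d * a)` — the odds of an event in the exposed group over
#' the odds in the reference group. If any cell is zero the Haldane-Anscombe
#' 0.5 continuity correction is applied to all four cells.
#'
#' @param a,b,c,d Non-negative cell counts (see convention above).
#' @param conf_level Confidence level for the Woolf (log-scale) interval.
#' @return A tibble with `odds_ratio`, `conf_low`, `conf_high`, `corrected`.
#' @examples
#' or_from_2x2(116, 446, 100, 270)$odds_ratio # 1.424
#' @export
or_from_2x2 <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    abort("All four cell counts must be non-negative numbers.",
          class = "engtraj_argument_error")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[["c"]] * cells[["b"]]) / (cells[["d"]] * cells[["a"]])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    odds_ratio = or,
    conf_low = exp(log(or) - z * se),
    conf_high = exp(log(or) + z * se),
    corrected = corrected
  )
}

#' Expand 2x2 counts into a subject-level data frame
#'
#' Utility used in examples and tests to reconstruct individual records from
#' aggregate counts: `a`/`b` reference-group events/non-events, `c`/`d`
#' exposed-group events/non-events (the [or_from_2x2()] convention).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A tibble with columns `exposed` and `event` (0/1).
#' @export
expand_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    exposed = rep(c(0L, 0L, 1L, 1L), times = c(a, b, c, d)),
    event = rep(c(1L, 0L, 1L, 0L), times = c(a, b, c, d))
  )
}

#' Stepwise covariate selection by AIC
#'
#' Greedy bidirectional stepwise selection: starting from the forced-terms
#' model, every single candidate addition and every single candidate drop is
#' evaluated at each step, and the move with the lowest AIC is accepted if it
#' improves on the current model; selection stops when no move does. Forced
#' terms (e.g. the trajectory-group indicators) are never dropped. Ties are
#' broken toward the smaller model, then alphabetically by term, so the
#' procedure is deterministic. Candidates whose addition makes the design
#' rank deficient are skipped with a warning.
#'
#' @param data A data frame with outcome, forced terms and candidates.
#' @param outcome Name of the binary outcome column.
#' @param forced Character vector of terms always kept in the model.
#' @param candidates Character vector of candidate covariate names.
#' @return A list with `fit` (the final `engtraj_logit`) and `trace` (a
#'   tibble of accepted moves: `step`, `action`, `term`, `aic_before`,
#'   `aic_after`).
#' @export
stepwise_aic <- function(data, outcome, forced = character(),
                         candidates = character()) {
  # complete cases over ALL columns in play, so AICs are comparable
  data <- prepare_model_frame(data, outcome, union(forced, candidates),
                              binary_outcome = TRUE)
  current <- character()
  fit_cached <- fit_logistic(data, outcome, forced)
  current_aic <- fit_cached$aic
  trace <- list()
  bad <- character()
  repeat {
    moves <- dplyr::bind_rows(
      if (length(setdiff(candidates, c(current, bad)))) {
        tibble::tibble(action = "add",
                       term = setdiff(candidates, c(current, bad)))
      },
      if (length(current)) tibble::tibble(action = "drop", term = current)
    )
    if (nrow(moves) == 0) break
    moves$aic <- NA_real_
    for (i in seq_len(nrow(moves))) {
      trial <- if (moves$action[i] == "add") c(current, moves$term[i]) else
        setdiff(current, moves$term[i])
      aic_i <- tryCatch(
        fit_logistic(data, outcome, c(forced, trial))$aic,
        engtraj_rank_error = function(e) {
          if (moves$action[i] == "add") {
            warn(sprintf(
              "Candidate `%s` is collinear with the current model; skipped.",
              moves$term[i]))
            bad <<- union(bad, moves$term[i])
          }
          NA_real_
        },
        engtraj_separation_error = function(e) NA_real_
      )
      moves$aic[i] <- aic_i
    }
    moves <- moves[!is.na(moves$aic), , drop = FALSE]
    if (nrow(moves) == 0) break
    # lowest AIC; ties -> smaller model (drops first), then alphabetical
    moves <- moves[order(moves$aic,
                         match(moves$action, c("drop", "add")),
                         moves$term), , drop = FALSE]
    if (moves$aic[1] >= current_aic - 1e-8) break
    step_no <- length(trace) + 1L
    trace[[step_no]] <- tibble::tibble(
      step = step_no, action = moves$action[1], term = moves$term[1],
      aic_before = current_aic, aic_after = moves$aic[1])
    current <- if (moves$action[1] == "add") c(current, moves$term[1]) else
      setdiff(current, moves$term[1])
    current_aic <- moves$aic[1]
  }
  list(
    fit = fit_logistic(data, outcome, c(forced, sort(current))),
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), action = character(),
                     term = character(), aic_before = double(),
                     aic_after = double())
  )
}
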