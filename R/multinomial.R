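#' Multinomial logistic regression of cluster membership
#'
#' Baseline-category logit model linking trajectory-cluster membership to
#' baseline characteristics, fitted by maximum likelihood via
#' [nnet::multinom()]. The reference category defaults to cluster 1, which
#' after [relabel_by_size()] is the largest cluster (the short-term users),
#' so every contrast reads "odds of being in cluster g rather than the
#' reference". Wald standard errors come from the inverse observed
#' information (the optimizer's Hessian).
#'
#' @param data A data frame with the model terms.
#' @param labels Integer or factor cluster labels aligned to `data` rows
#'   (alternatively the name of a column in `data`).
#' @param terms Character vector of predictor column names.
#' @param reference Reference cluster label. Default `1`.
#' @return An object of class `engtraj_multinom`: list with `fit` (the
#'   multinom object), `coefficients` and `std_errors` ((G-1) x p matrices),
#'   `reference`, `levels`, `n`, `loglik`, `aic`.
#' @export
fit_multinomial <- function(data, labels, terms = character(),
                            reference = 1L) {
  stopifnot(is.data.frame(data))
  if (is.character(labels) && length(labels) == 1L && labels %in% names(data)) {
    labels <- data[[labels]]
  }
  if (length(labels) != nrow(data)) {
    abort("`labels` must have one entry per row of `data`.",
          class = "engtraj_argument_error")
  }
  y <- factor(labels)
  if (nlevels(y) < 2) {
    abort("Need at least 2 clusters to fit a membership model.",
          class = "engtraj_argument_error")
  }
  if (!as.character(reference) %in% levels(y)) {
    abort(sprintf("Reference cluster `%s` not present in labels.", reference),
          class = "engtraj_argument_error")
  }
  y <- stats::relevel(y, ref = as.character(reference))
  df <- data[, terms, drop = FALSE]
  df$.cluster <- y
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  f <- terms_formula(".cluster", terms)
  check_full_rank(terms_formula(".cluster", terms), df)
  fit <- nnet::multinom(f, data = df, Hess = TRUE, trace = FALSE,
                        maxit = 500L, reltol = 1e-12)
  sm <- summary(fit)
  coefs <- sm$coefficients
  ses <- sm$standard.errors
  if (is.null(dim(coefs))) { # two-cluster case collapses to a vector
    coefs <- matrix(coefs, nrow = 1,
                    dimnames = list(levels(y)[2], names(sm$coefficients)))
    ses <- matrix(ses, nrow = 1, dimnames = dimnames(coefs))
  }
  structure(
    list(fit = fit, coefficients = coefs, std_errors = ses,
         reference = as.character(reference), levels = levels(y),
         n = nrow(df), loglik = -sm$deviance / 2, aic = sm$AIC),
    class = "engtraj_multinom"
  )
}

#' @export
odds_ratios.engtraj_multinom <- function(fit, conf_level = 0.95) {
  rows <- lapply(rownames(fit$coefficients), function(cl) {
    tab <- wald_or_table(colnames(fit$coefficients),
                         fit$coefficients[cl, ],
                         fit$std_errors[cl, ], conf_level)
    tibble::add_column(tab, cluster = cl, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.engtraj_multinom <- function(x, ...) {
  cat(sprintf(
    "Multinomial membership model: %d categories (reference %s), n = %d\n",
    length(x$levels), x$reference, x$n))
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  invisible(x)
}

#' Tidy a multinomial membership fit
#'
#' @param x An `engtraj_multinom` object.
#' @param ... Unused.
#' @return `tidy()`: odds-ratio table with one row per (cluster, term);
#'   `glance()`: one row with `n`, `loglik`, `aic`, `n_clusters`.
#' @export
tidy.engtraj_multinom <- function(x, ...) odds_ratios(x)

#' @rdname tidy.engtraj_multinom
#' @export
glance.engtraj_multinom <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, aic = x$aic,
                 n_clusters = length(x$levels))
}

#' Predicted class probabilities
#'
#' @param object An `engtraj_multinom` object.
#' @param newdata Optional data frame of predictors; defaults to the
#'   training frame.
#' @param ... Unused.
#' @return Matrix of class probabilities, one row per subject, columns in
#'   `object$levels` order; rows sum to 1.
#' @export
predict_probs <- function(object, newdata = NULL, ...) {
  stopifnot(inherits(object, "engtraj_multinom"))
  p <- if (is.null(newdata)) {
    stats::predict(object$fit, type = "probs")
  } else {
    stats::predict(object$fit, newdata = newdata, type = "probs")
  }
  if (is.null(dim(p))) { # two-category case returns P(level 2)
    p <- cbind(1 - p, p)
    colnames(p) <- object$levels
  }
  p
}

#' Univariate screening of candidate covariates
#'
#' For each candidate covariate a single-covariate multinomial model of the
#' cluster labels is compared against the intercept-only model by a
#' likelihood-ratio test; covariates with p below `alpha` form the candidate
#' pool passed to stepwise selection. Constant covariates carry no
#' information and are excluded with a warning.
#'
#' @param data A data frame of covariates.
#' @param labels Cluster labels aligned to rows of `data`.
#' @param candidates Character vector of covariate names to screen.
#' @param alpha Inclusion threshold on the LR-test p-value. Default 0.05.
#' @return A tibble with `term`, `lr_stat`, `df`, `p_value`, `keep`; the
#'   selected pool is `term[keep]`.
#' @export
univariate_screen <- function(data, labels, candidates, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  y <- factor(labels)
  G <- nlevels(y)
  rows <- lapply(candidates, function(term) {
    x <- data[[term]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      warn(sprintf("Covariate `%s` is constant; excluded from screening.",
                   term))
      return(tibble::tibble(term = term, lr_stat = 0, df = G - 1L,
                            p_value = 1, keep = FALSE))
    }
    df1 <- data.frame(.cluster = y[ok], x = x[ok])
    null_fit <- nnet::multinom(.cluster ~ 1, data = df1, trace = FALSE)
    alt_fit <- nnet::multinom(.cluster ~ x, data = df1, trace = FALSE,
                              maxit = 500L, reltol = 1e-12)
    lr <- null_fit$deviance - alt_fit$deviance
    dof <- (G - 1L) * 1L
    p <- pchisq(lr, df = dof, lower.tail = FALSE)
    tibble::tibble(term = term, lr_stat = lr, df = dof, p_value = p,
                   keep = p < alpha)
  })
  dplyr::bind_rows(rows)
}
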