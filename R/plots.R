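#' Plot per-cluster weekly log-in profiles
#'
#' Line plot of mean weekly log-ins by cluster — the standard way of showing
#' how engagement-trajectory groups differ over follow-up.
#'
#' @param profile A tibble from [weekly_profile()].
#' @param weeks Number of leading weeks to show (early weeks carry most of
#'   the structure). Default 16; use 52 for the full year.
#' @return A ggplot object.
#' @export
plot_weekly_profile <- function(profile, weeks = 16) {
  stopifnot(all(c("cluster", "week", "mean_logins") %in% names(profile)))
  profile |>
    dplyr::filter(.data$week <= weeks) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$week, y = .data$mean_logins,
                                 colour = factor(.data$cluster))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_y_continuous(limits = c(0, 7)) +
    ggplot2::labs(x = "Week since enrollment", y = "Mean log-in days",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.engtraj_ps <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$k, y = .data$ps_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$ps_mean - .data$ps_sd, 0),
      ymax = pmin(.data$ps_mean + .data$ps_sd, 1))) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = tidy(object)$k) +
    ggplot2::labs(x = "Number of clusters k", y = "Prediction strength") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.engtraj_fpca <- function(object, components = NULL, ...) {
  K <- components %||% object$n_components
  K <- min(K, object$n_components)
  d <- tibble::tibble(
    t = rep(object$grid, K + 1L),
    value = c(object$mean_fn,
              as.vector(t(object$eigenfunctions[seq_len(K), , drop = FALSE]))),
    fn = rep(c("mean", paste0("phi_", seq_len(K))),
             each = length(object$grid))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fn, scales = "free_y") +
    ggplot2::labs(x = "Scaled time", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
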