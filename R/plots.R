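#' Plot a forgetting curve and the optimal intensity
#'
#' Shows the recall probability decaying from the last review and, on a
#' second panel, the optimal reviewing intensity `q^(-1/2)(1 - m)` that it
#' induces.
#'
#' @param state A [memory_state()].
#' @param q Trade-off of the optimal scheduler.
#' @param horizon Days past the last review to display.
#' @return A ggplot object.
#' @export
plot_forgetting_curve <- function(state, q = 1, horizon = 30) {
  dt <- seq(0, horizon, length.out = 200)
  df <- tibble::tibble(
    t = state$t_last + dt,
    m = exp(-state$n * dt),
    u = memorize_intensity(exp(-state$n * dt), q)
  ) |>
    tidyr::pivot_longer(c("m", "u"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          m = "recall probability m(t)",
                          u = "optimal intensity u(t) [1/day]"
                        ))) +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of forgetting rates across scheduler groups
#'
#' The headline comparison figure: distribution of the (normalised)
#' empirical forgetting rate in each likelihood-matched scheduler group.
#' Lower is better.
#'
#' @param grouped Output of [assign_groups()].
#' @param metric Column to plot (default `"n_hat_norm"`).
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(grouped, metric = "n_hat_norm") {
  df <- grouped[is.finite(grouped[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.alpha = 0.25) +
    ggplot2::labs(x = NULL, y = "normalised empirical forgetting rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.memory_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "objective evaluation", y = "best loss so far") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
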