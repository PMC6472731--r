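# ggplot2 presentations of the main result types.

#' Plot a model-comparison table
#'
#' Dot-and-error display of each model's mean relative AIC across
#' datasets, with the "no support" threshold marked.
#'
#' @param object An `observer_comparison` from [delta_aic_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot observer_comparison
#' @export
autoplot.observer_comparison <- function(object, ...) {
  s <- attr(object, "summary")
  s$model <- factor(s$model, levels = rev(s$model))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean_delta_aic, y = .data$model)) +
    ggplot2::geom_vline(xintercept = attr(object, "no_support_at"),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(.data$mean_delta_aic - .data$se_delta_aic, 0),
                   xmax = .data$mean_delta_aic + .data$se_delta_aic),
      height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean ΔAIC (relative to best model)", y = NULL)
}

#' Plot a model-recovery matrix
#'
#' Heat map of mean relative AIC with the winning (recovered) model
#' marked per generator row.
#'
#' @param object A `recovery_matrix` from [model_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_matrix
#' @export
autoplot.recovery_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$generator,
                                   fill = .data$delta_aic)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$winner, ], colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "mean ΔAIC") +
    ggplot2::labs(x = "fitted model", y = "generating model") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a psychometric fit
#'
#' Binned proportions of "clockwise" responses per reliability with the
#' fitted cumulative-Gaussian curves.
#'
#' @param object A `psychometric_fit` from [fit_psychometric()].
#' @param n_bins Number of orientation bins for the empirical points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, n_bins = 9, ...) {
  data <- object$data
  binned <- data |>
    mutate(bin = cut(.data$orientation, n_bins)) |>
    group_by(.data$reliability, .data$bin) |>
    summarise(orientation = mean(.data$orientation),
              p_cw = mean(.data$response_cw), n = dplyr::n(),
              .groups = "drop")
  grid <- tidyr::expand_grid(
    orientation = seq(min(data$orientation), max(data$orientation),
                      length.out = 201),
    reliability = c("low", "high"))
  grid$p_cw <- ifelse(grid$reliability == "high",
                      .p_clockwise(grid$orientation, object$sigma_high),
                      .p_clockwise(grid$orientation, object$sigma_low))
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$orientation, y = .data$p_cw,
                                       colour = .data$reliability)) +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "orientation (deg)", y = "P(clockwise)")
}

#' Plot a decision-error distribution
#'
#' Histogram of the simulated decision-variable error with the
#' moment-fitted Gaussian overlaid.
#'
#' @param object A `delta_d_sim` from [simulate_delta_d()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_d_sim
#' @export
autoplot.delta_d_sim <- function(object, bins = 80, ...) {
  df <- tibble(delta_d = object$delta_d)
  m <- object$summary$mean
  s <- object$summary$sd
  grid <- tibble(delta_d = seq(min(df$delta_d), max(df$delta_d),
                               length.out = 301))
  grid$density <- dnorm(grid$delta_d, m, s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_d)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$density)) +
    ggplot2::labs(x = expression(Delta * d), y = "density",
                  subtitle = paste(object$kinds, collapse = " + "))
}
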