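#' Plot a differential methylation fit
#'
#' Abundance versus methylation fold-change overview: each tested feature at
#' its estimated abundance (log10) and log2 risk ratio, significant features
#' (adjusted p below `alpha`) highlighted. Abundant features show a narrower
#' fold-change spread, so calls at matched abundance stand out.
#'
#' @param object A [qnb_test()] fit.
#' @param alpha Adjusted-p significance cutoff for highlighting (default
#'   0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qnb_fit
#' @export
autoplot.qnb_fit <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$status == "tested", is.finite(.data$log2_rr)) |>
    dplyr::mutate(significant = !is.na(.data$p_adjusted) &
                    .data$p_adjusted < alpha)
  ggplot2::ggplot(df, ggplot2::aes(log10(.data$q_hat), .data$log2_rr,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log10 abundance (q)",
      y = "log2 methylation risk ratio",
      colour = sprintf("adj. p < %g", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the fitted raw-variance scatter
#'
#' Common-scale replicate variance against abundance for each sample type and
#' fitting group, with the smoothed surface evaluated at the fitted points
#' overlaid. Both axes are logged; the mean-variance trend the smoother
#' captures is the heart of the small-sample inference.
#'
#' @param object A [fit_variance_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qnb_variance_model
#' @export
autoplot.qnb_variance_model <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$w_hat > 0, .data$q_hat > 0) |>
    dplyr::mutate(fitted_w = .data$v_hat + .data$z)
  ggplot2::ggplot(df, ggplot2::aes(.data$q_hat, .data$w_hat)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$fitted_w),
                        colour = "firebrick", size = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(sample_type ~ group) +
    ggplot2::labs(x = "abundance (q)",
                  y = "common-scale variance w (points) / fit (red)") +
    ggplot2::theme_minimal()
}

#' Plot a genuine-vs-mock swop curve
#'
#' @param curve A [swop_curve()] tibble.
#' @return A ggplot object with the identity line for reference.
#' @export
plot_swop_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$mock_fraction,
                                      .data$genuine_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "fraction called on mock (background)",
                  y = "fraction called on genuine") +
    ggplot2::theme_minimal()
}
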