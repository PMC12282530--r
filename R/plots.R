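#' Plot the hierarchical response surface
#'
#' Heat map of predicted branching events per inflorescence (log scale) over
#' the within-pair effect grid: with no masking (`theta_int = 0`) the
#' contours are straight anti-diagonals; masking bends them so transects
#' flatten as the other pair's effect grows.
#'
#' @param object A `hier_surface` from [response_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hier_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$phi_plt, .data$phi_sep,
                                       fill = log10(.data$branching))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 branching\nevents/infl.") +
    ggplot2::labs(
      x = "PLT-pair effect (log-fold)",
      y = "SEP-pair effect (log-fold)",
      title = sprintf("Hierarchical response surface (theta_int = %.3f)",
                      attr(object, "theta_int"))) +
    ggplot2::theme_minimal()
}

#' Plot background-rescaling lines
#'
#' One panel of points and total-least-squares lines per genetic background:
#' log phenotype of the focal-pair combinations in that background against
#' the wild-type background. A multiplicative model gives slope 1 in every
#' background; decreasing slopes indicate masking.
#'
#' @param rescaling Output of [background_rescaling()].
#' @return A ggplot object.
#' @export
plot_background_rescaling <- function(rescaling) {
  pts <- rescaling |>
    dplyr::mutate(points = purrr::map(.data$points, ~ .x)) |>
    tidyr::unnest("points")
  ggplot2::ggplot(pts, ggplot2::aes(.data$logm_wt, .data$logm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      data = rescaling,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
      colour = "black", linetype = 2) +
    ggplot2::facet_wrap(~background) +
    ggplot2::labs(x = "log mean branching, WT background",
                  y = "log mean branching, mutant background") +
    ggplot2::theme_minimal()
}

#' Plot genotype-season estimates against model predictions
#'
#' @param mle_table Output of [genotype_season_mle()].
#' @param predicted Numeric vector of predicted means (one per row), e.g.
#'   from [predict_log_mean()] exponentiated.
#' @return A ggplot object (log(1+x) scales, 1:1 reference line).
#' @export
plot_predicted_vs_mle <- function(mle_table, predicted) {
  df <- tibble::tibble(mle = mle_table$mean, predicted = predicted,
                       wide_ci = mle_table$wide_ci)
  ggplot2::ggplot(df[!df$wide_ci, ],
                  ggplot2::aes(log1p(.data$predicted), log1p(.data$mle))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log(1 + predicted mean branching)",
                  y = "log(1 + MLE mean branching)") +
    ggplot2::theme_minimal()
}
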