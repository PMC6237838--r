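#' Bar chart of mixing metrics by treatment
#'
#' Group means with standard-deviation error bars for one mixing statistic,
#' in the familiar per-treatment bar layout.
#'
#' @param metrics Per-aquarium metrics table.
#' @param response One of `"l_max_mm"`, `"l_med_mm"`, `"l_mean_mm"`,
#'   `"sbr_mm"`.
#' @return A ggplot object.
#' @export
plot_mixing_metrics <- function(metrics, response = "l_max_mm") {
  if (!response %in% names(metrics)) {
    stop("no column `", response, "` in metrics", call. = FALSE)
  }
  summ <- metrics |>
    dplyr::filter(!is.na(.data[[response]])) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(mean = mean(.data[[response]]),
                     sd = stats::sd(.data[[response]]), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$treatment, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd), width = 0.25) +
    ggplot2::labs(x = NULL, y = paste(response, "(mean ± SD)")) +
    ggplot2::theme_minimal()
}

#' Depth-profile histogram
#'
#' Luminophore pixel counts by burial depth below the flattened interface.
#'
#' @param profile A `depth_profile`.
#' @param binwidth_mm Aggregation bin width (mm).
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(profile, binwidth_mm = 1) {
  df <- profile |>
    dplyr::mutate(bin = floor(.data$depth_mm / binwidth_mm) * binwidth_mm) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pixels = sum(.data$n_pixels), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_pixels, y = .data$bin)) +
    ggplot2::geom_col(orientation = "y", fill = "hotpink3") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "luminophore pixels", y = "depth below interface (mm)") +
    ggplot2::theme_minimal()
}

#' Nutrient time-series plot
#'
#' Mean concentration per treatment over the sampling days, one panel per
#' nutrient.
#'
#' @param nutrients Validated nutrient table.
#' @return A ggplot object.
#' @export
plot_nutrient_series <- function(nutrients) {
  long <- nutrients |>
    tidyr::pivot_longer(dplyr::all_of(NUTRIENT_COLS),
                        names_to = "nutrient", values_to = "mg_l") |>
    dplyr::group_by(.data$treatment, .data$day, .data$nutrient) |>
    dplyr::summarise(mg_l = mean(.data$mg_l), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$mg_l,
                                     colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~nutrient, scales = "free_y") +
    ggplot2::labs(x = "day", y = "concentration (mg/L)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA biplot of the nutrient ordination
#'
#' Scores coloured by treatment with variable loadings overlaid as arrows.
#'
#' @param object A [pca_ordination()] (e.g. from [run_nutrient_pca()]).
#' @param arrow_scale Multiplier applied to the loading arrows.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_ordination
#' @export
autoplot.pca_ordination <- function(object, arrow_scale = NULL, ...) {
  sc <- object$scores
  ld <- object$loadings
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) /
      max(abs(c(ld$PC1, ld$PC2)))
  }
  vf <- object$variance_fraction
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("treatment" %in% names(sc)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$treatment))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                   yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30") +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * arrow_scale * 1.08,
                   y = .data$PC2 * arrow_scale * 1.08,
                   label = .data$variable),
      size = 3, colour = "grey30") +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * vf[2])) +
    ggplot2::theme_minimal()
}
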