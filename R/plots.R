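#' Plot per-strain category proportions
#'
#' Stacked-bar analogue of the per-strain pie charts: the fraction of cells
#' with each structure category, with n annotated.
#'
#' @param props Tibble from [category_proportions()].
#' @return A ggplot.
#' @export
plot_category_proportions <- function(props) {
  ggplot2::ggplot(props,
                  ggplot2::aes(x = .data$strain, y = .data$fraction,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = dplyr::distinct(props, .data$strain, .data$n),
      ggplot2::aes(x = .data$strain, y = -0.04,
                   label = paste0("n=", .data$n)),
      inherit.aes = FALSE, size = 3) +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "fraction of cells", fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot feature distributions per strain
#'
#' Box plots of filament length, filament intensity and brightest-focus
#' intensity by strain (normalize first with [normalize_to_wt()] to mirror
#' the usual presentation).
#'
#' @param records A `cell_records` tibble.
#' @return A ggplot.
#' @export
plot_intensity_distributions <- function(records) {
  long <- tidyr::pivot_longer(
    records,
    cols = c("filament_length_px", "filament_intensity", "spot_intensity"),
    names_to = "feature", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strain, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname plot_intensity_distributions
#' @param object A `cell_records` tibble.
#' @param ... Unused.
#' @method autoplot cell_records
#' @export
autoplot.cell_records <- function(object, ...) {
  plot_intensity_distributions(object)
}

#' Plot an intensity-ratio profile with region calls
#'
#' @param ratio Tibble from [intensity_ratio()].
#' @param regions Optional tibble from [call_interaction_region()].
#' @param threshold Attenuation threshold drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_ratio_profile <- function(ratio, regions = NULL, threshold = 0.5) {
  p <- ggplot2::ggplot(ratio[!is.na(ratio$ratio), ],
                       ggplot2::aes(x = .data$residue, y = .data$ratio)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "I / I0") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2)
  }
  p
}

#' Plot a Calpha secondary-shift profile
#'
#' @param delta Tibble from [secondary_shift()].
#' @param cutoff Disorder cutoff (ppm) drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_secondary_shift <- function(delta, cutoff = 0.5) {
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$residue,
                                      y = .data$delta_ca)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff),
                        linetype = "dashed") +
    ggplot2::labs(x = "residue",
                  y = expression(Delta * delta * " C" * alpha * " (ppm)")) +
    ggplot2::theme_minimal()
}
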