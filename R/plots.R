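# ggplot2 views of the main result types.

#' Plot observed versus shuffled fold energies
#'
#' @param object An `ensemble_deviation`.
#' @param ... Unused.
#' @return A ggplot: shuffled-ensemble energies with the observed value marked.
#' @export
autoplot.ensemble_deviation <- function(object, ...) {
  df <- tidy(object)
  shuffled <- dplyr::filter(df, .data$role == "shuffled")
  ggplot2::ggplot(shuffled, ggplot2::aes(x = .data$mfe)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = object$observed_mfe, colour = "firebrick", linewidth = 1
    ) +
    ggplot2::labs(
      x = "fold energy", y = "shuffles",
      title = sprintf("deviation = %.3g", object$deviation)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sensor site distributions across hybridization trials
#'
#' @param object A `hybrid_trials`.
#' @param ... Unused.
#' @return A ggplot of per-trial sensor-site counts, one panel per sensor.
#' @export
autoplot.hybrid_trials <- function(object, ...) {
  df <- dplyr::filter(object$trials, !.data$failed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sites)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~sensor, scales = "free") +
    ggplot2::labs(x = "sensor sites per duplex", y = "trials") +
    ggplot2::theme_minimal()
}

#' Plot Alu category proportions by region type
#'
#' @param proportions Tibble from [category_proportions()].
#' @return A stacked-bar ggplot of category shares per region type.
#' @export
plot_category_proportions <- function(proportions) {
  ggplot2::ggplot(
    proportions,
    ggplot2::aes(x = .data$region_type, y = .data$proportion, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "proportion of regions", fill = "Alu content") +
    ggplot2::theme_minimal()
}

#' Plot per-sensor site counts for a region set
#'
#' @param sites Long tibble from [count_sensor_sites_for_regions()].
#' @return A boxplot of per-region sensor-site counts by sensor.
#' @export
plot_sensor_sites <- function(sites) {
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$sensor, y = .data$sites)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "dsRNA sensor sites per region") +
    ggplot2::theme_minimal()
}
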