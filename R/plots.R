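#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

zone_fill_scale <- function() {
  ggplot2::scale_fill_manual(values = c(
    "I" = "grey40", "1" = "#d73027", "2" = "#fc8d59", "3" = "#fee090",
    "4" = "#91bfdb", "5" = "#4575b4", "none" = "grey85"
  ), na.value = "grey90")
}

#' Heatmap of a zone-pair trans-contact map
#'
#' @param object A `zone_pair_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zone_pair_map
#' @export
autoplot.zone_pair_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$zone_b, y = .data$zone_a, fill = .data$mean_contacts
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$map))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "zone", y = "zone", fill = "mean trans\ncontacts",
      title = "Average interchromosomal OR contacts by zone pair"
    ) +
    ggplot2::theme_minimal()
}

#' Densities by zone with the fitted trend
#'
#' @param object A `zonal_trend`.
#' @param table Optional density table used for the statistic (adds jitter
#'   points when supplied).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zonal_trend
#' @export
autoplot.zonal_trend <- function(object, table = NULL, ...) {
  p <- ggplot2::ggplot(
    object$per_zone,
    ggplot2::aes(x = factor(.data$zone), y = .data$mean_density)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(
      x = "zonal identity", y = "mean gene-body density",
      title = sprintf("Dorsoventral gradient: trend = %.2f (p = %.2g)",
                      object$trend, object$p_value)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(table)) {
    p <- p + ggplot2::geom_jitter(
      data = table |> filter(!is.na(.data$zone)),
      ggplot2::aes(x = factor(.data$zone), y = .data$density),
      width = 0.2, alpha = 0.4, size = 0.6
    )
  }
  p
}

#' Metagene heatmap over gene bodies with flanks
#'
#' @param mat A `metagene_matrix` from [scaled_metagene_matrix()].
#' @param trans Transformation of the fill values (default `log1p`).
#' @return A ggplot.
#' @export
plot_metagene <- function(mat, trans = log1p) {
  df <- as_tibble(as.data.frame(unclass(mat)), .name_repair = "minimal") |>
    mutate(gene_id = factor(rownames(mat), levels = rev(rownames(mat)))) |>
    tidyr::pivot_longer(-"gene_id", names_to = "offset",
                        values_to = "density") |>
    mutate(offset = as.numeric(.data$offset))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$offset, y = .data$gene_id, fill = trans(.data$density)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(
      x = "position (bp; body scaled)", y = NULL,
      title = "Scaled gene-body signal with unscaled flanks"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Spatial map of zonal spot assignments
#'
#' @param assignment A `spot_assignment`.
#' @return A ggplot of spots at their grid coordinates, colored by zone.
#' @export
plot_spot_zones <- function(assignment) {
  ggplot2::ggplot(assignment, ggplot2::aes(
    x = .data$x, y = -.data$y, fill = .data$zone
  )) +
    ggplot2::geom_tile(color = "white", linewidth = 0.2) +
    zone_fill_scale() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "assigned zone",
      title = "Zonal spot assignment (dorsal at top)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Choice frequencies by zonal identity of the chosen OR
#'
#' @param tissue An `or_tissue` with mature neurons.
#' @return A stacked-bar ggplot of chosen-OR zonal identity per cell zone.
#' @export
plot_choice_composition <- function(tissue) {
  freq <- choice_frequencies(tissue) |>
    group_by(.data$dv_zone, .data$zone_label) |>
    summarise(freq = sum(.data$freq), .groups = "drop")
  ggplot2::ggplot(freq, ggplot2::aes(
    x = factor(.data$dv_zone), y = .data$freq, fill = .data$zone_label
  )) +
    ggplot2::geom_col() +
    zone_fill_scale() +
    ggplot2::labs(
      x = "cell zone", y = "fraction of mature neurons",
      fill = "chosen OR\nidentity",
      title = "Zonal identity of the chosen OR by cell position"
    ) +
    ggplot2::theme_minimal()
}
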