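#' Plot population corridors
#'
#' Mean +/- k SD corridor ribbons as a function of station, faceted by rib,
#' coloured by sex, for one cross-sectional property.
#'
#' @param object a [build_corridors()] table.
#' @param property one of `"Tt.Ar"`, `"Ct.Ar"`, `"Es.Ar"`, `"Imax"`,
#'   `"Imin"`, `"Irat"`.
#' @param k corridor half-width in SDs.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rib_corridors
#' @export
autoplot.rib_corridors <- function(object, property = "Tt.Ar", k = 1, ...) {
  band <- corridor_band(object, k = k)
  band <- band[band$property == property, ]
  ggplot2::ggplot(band, ggplot2::aes(x = .data$station_pct)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper, fill = .data$sex),
      alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = .data$sex)) +
    ggplot2::facet_wrap(~rib, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "Station (% of rib length, vertebral to sternal)",
      y = property_axis_label(property),
      title = sprintf("%s population corridors (mean ± %g SD)", property, k)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay a model's traces on population corridors
#'
#' The audit figure: grey mean +/- k SD corridor band per rib with the
#' model's property trace drawn over it, faceted by rib.
#'
#' @param corridors a [build_corridors()] table.
#' @param record a model record ([hbm_rib_to_record()] rows for one model).
#' @param property property to draw.
#' @param k corridor half-width in SDs.
#' @return A ggplot object.
#' @export
plot_corridor_overlay <- function(corridors, record, property = "Tt.Ar", k = 1) {
  sex <- unique(record$sex)
  stopifnot(length(sex) == 1L)
  band <- corridor_band(corridors, k = k)
  band <- band[band$property == property & band$sex == sex &
                 band$rib %in% unique(record$rib), ]
  col <- names(property_columns)[match(property, property_columns)]
  trace <- tibble::tibble(
    rib = record$rib, station_pct = record$station_pct, value = record[[col]]
  )
  ggplot2::ggplot(band, ggplot2::aes(x = .data$station_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "grey40") +
    ggplot2::geom_line(data = trace, ggplot2::aes(y = .data$value), colour = "firebrick") +
    ggplot2::facet_wrap(~rib, labeller = ggplot2::label_both, scales = "free_y") +
    ggplot2::labs(
      x = "Station (% of rib length)",
      y = property_axis_label(property),
      title = sprintf("%s model (%s) vs %s population corridor (± %g SD)",
                      unique(record$model)[1L], sex, property, k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a comparison table
#'
#' Stacked percentage of rib length above / within / below the 1 SD corridor
#' per rib, faceted by property and model.
#'
#' @param object a [comparison_table()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rib_comparison
#' @export
autoplot.rib_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("pct_high", "pct_in", "pct_low"),
    names_to = "bin", values_to = "pct"
  )
  long$bin <- factor(long$bin, levels = c("pct_high", "pct_in", "pct_low"),
                     labels = c("> +1 SD", "within 1 SD", "< -1 SD"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$rib), y = .data$pct,
                                     fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(model ~ property) +
    ggplot2::scale_fill_manual(values = c("#d95f02", "#999999", "#1b9e77")) +
    ggplot2::labs(x = "Rib", y = "% of rib length", fill = NULL) +
    ggplot2::theme_minimal()
}

property_axis_label <- function(property) {
  switch(property,
    Tt.Ar = "Tt.Ar (mm²)", Ct.Ar = "Ct.Ar (mm²)",
    Es.Ar = "Es.Ar (mm²)",
    Imax = "Imax (mm⁴)", Imin = "Imin (mm⁴)",
    Irat = "Irat = ln(Imax/Imin)",
    property
  )
}
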