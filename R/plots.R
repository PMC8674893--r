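# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_smooth
#'   geom_col labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot daily oxythermal metrics
#'
#' TDO3 and habitat thickness over the season, one panel per lake.
#'
#' @param object an [oxythermal_daily()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot oxythermal_daily
#' @export
autoplot.oxythermal_daily <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("tdo3", "thickness"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$day, y = .data$value, colour = .data$metric)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~lake_id) +
    labs(x = "day", y = NULL,
         title = "Daily oxythermal metrics",
         subtitle = "TDO3 (°C) and habitat thickness (m)") +
    theme_minimal()
}

#' Biplot of a redundancy analysis
#'
#' Site and predictor scores on the first two constrained axes.
#'
#' @param object an [rda_genetics()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rda_result
#' @export
autoplot.rda_result <- function(object, ...) {
  sc <- vegan::scores(object$ordination, display = c("sites", "bp"),
                      choices = 1:2)
  sites <- as_tibble(sc$sites, rownames = "population")
  arrows <- as_tibble(sc$biplot, rownames = "predictor")
  ggplot(sites, aes(x = .data$RDA1, y = .data$RDA2)) +
    geom_point() +
    ggplot2::geom_segment(
      data = arrows, aes(x = 0, y = 0, xend = .data$RDA1, yend = .data$RDA2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue") +
    ggplot2::geom_text(data = arrows,
                       aes(label = .data$predictor), colour = "steelblue",
                       vjust = -0.6, size = 3) +
    labs(title = "Redundancy analysis",
         subtitle = paste0("constrained fraction ",
                           round(object$constrained, 2))) +
    theme_minimal()
}

#' Isolation-by-distance plot
#'
#' Linearized FST against pairwise geographic distance with a linear trend.
#'
#' @param fst a [pairwise_matrix()] of FST values (raw scale).
#' @param geo a [pairwise_matrix()] of distances in km.
#' @return a ggplot object.
#' @export
plot_ibd <- function(fst, geo) {
  d <- left_join(tidy(linearize_fst(fst)) |> dplyr::rename(lin_fst = "value"),
                 tidy(geo) |> dplyr::rename(km = "value"),
                 by = c("pop1", "pop2"))
  ggplot(d, aes(x = .data$km, y = .data$lin_fst)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "grey40") +
    labs(x = "geographic distance (km)", y = "FST / (1 - FST)",
         title = "Isolation by distance") +
    theme_minimal()
}

#' Stacked bar plot of standardized MHC haplotype frequencies
#'
#' @param object an [mhc_diversity()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mhc_diversity
#' @export
autoplot.mhc_diversity <- function(object, ...) {
  ggplot(object$frequencies,
         aes(x = .data$population, y = .data$std_freq, fill = .data$haplotype)) +
    geom_col() +
    labs(y = "standardized haplotype frequency", x = NULL,
         title = "MHC haplotype composition") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
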