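#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_jitter
#'   geom_errorbar geom_raster labs theme_minimal autoplot
#'   scale_fill_viridis_c stat_summary position_jitter
NULL

#' Plot an attenuation or second-derivative spectrum
#'
#' @param spectrum Tibble with `wavelength_nm` and one value column.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  vcol <- setdiff(names(spectrum), "wavelength_nm")[1]
  ggplot(spectrum, aes(x = .data$wavelength_nm, y = .data[[vcol]])) +
    geom_line(color = "steelblue") +
    labs(x = "wavelength (nm)", y = vcol) +
    theme_minimal()
}

#' Plot a perfusion (or any voxel) map
#'
#' @param map Numeric matrix (NA = masked).
#' @param title Plot title.
#' @return A ggplot raster.
#' @export
plot_cbf_map <- function(map, title = "CBF (ml/100g/min)") {
  df <- tidyr::expand_grid(x = seq_len(nrow(map)), y = seq_len(ncol(map)))
  df$value <- as.vector(map)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(title = title, x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}

#' Dot plot of a group comparison
#'
#' One point per animal with group mean +/- SD overlaid, mirroring the
#' per-metric panels of the study figures.
#'
#' @param object An `oxy_kw` object from [kruskal_wallis_pairwise()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oxy_kw
#' @export
autoplot.oxy_kw <- function(object, ...) {
  ggplot(object$data, aes(x = .data$group, y = .data$value)) +
    geom_jitter(width = 0.12, alpha = 0.7, color = "steelblue") +
    stat_summary(fun = mean, geom = "point", size = 3, color = "black") +
    stat_summary(fun.data = function(v)
      data.frame(y = mean(v), ymin = mean(v) - sd(v),
                 ymax = mean(v) + sd(v)),
      geom = "errorbar", width = 0.2) +
    labs(x = NULL, y = object$value,
         subtitle = sprintf("Kruskal-Wallis H = %.2f, p = %.3g",
                            object$omnibus$statistic_h, object$omnibus$p)) +
    theme_minimal()
}

#' Plot disease-score trajectories
#'
#' @param scores Long tibble with `day`, `total` and a grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return A ggplot of group mean daily scores.
#' @export
plot_disease_course <- function(scores, group = "group") {
  ggplot(scores, aes(x = .data$day, y = .data$total,
                     color = .data[[group]])) +
    stat_summary(fun = mean, geom = "line") +
    stat_summary(fun = mean, geom = "point", size = 1.5) +
    labs(x = "day post-induction", y = "disease score (0-15 scale)",
         color = NULL) +
    theme_minimal()
}
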