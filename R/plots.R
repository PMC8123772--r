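#' Plot a scalar map
#'
#' Renders a `scalar_map` as a raster with the jet palette, matching the
#' colors of [jet_quantize()].
#'
#' @param object A `scalar_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$values)),
                    col = seq_len(ncol(object$values)))
  df$value <- as.vector(object$values)
  pal <- jet_palette()
  cols <- grDevices::rgb(pal[, 1], pal[, 2], pal[, 3], maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = cols) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste(object$scheme, object$band, sep = " / "),
                  x = NULL, y = NULL, fill = "power") +
    ggplot2::theme_minimal()
}

#' Plot per-cycle experiment metrics
#'
#' @param object A `distress_experiment`.
#' @param ... Unused.
#' @return A ggplot object: per-cycle Se/Sp/Acc with mean lines.
#' @export
autoplot.distress_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object$cycles, c("se", "sp", "acc"),
                              names_to = "metric", values_to = "percent")
  long$metric <- factor(toupper(long$metric), levels = c("SE", "SP", "ACC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$percent,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$cycle)) +
    ggplot2::labs(x = "validation cycle", y = "percent", colour = NULL) +
    ggplot2::theme_minimal()
}
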