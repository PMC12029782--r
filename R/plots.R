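#' Plot a plate image with optional mask outlines
#'
#' Renders the grayscale plate raster; colony (`BAC`) and halo (`AS`) mask
#' outlines are overlaid when supplied.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param masks optional named list (`BAC`, `AS`) of logical-mask lists, as
#'   from [polygons_to_masks()] or [segment_reference()].
#' @param downsample keep every k-th pixel for display; default adapts to
#'   roughly a 400 px grid.
#' @return a ggplot object.
#' @export
plot_plate <- function(image, masks = NULL, downsample = NULL) {
  if (is.null(downsample)) downsample <- max(1L, floor(nrow(image) / 400))
  ridx <- seq(1, nrow(image), by = downsample)
  cidx <- seq(1, ncol(image), by = downsample)
  df <- expand.grid(row = ridx, col = cidx)
  df$value <- image[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(masks)) {
    outline <- purrr::imap_dfr(masks, function(lst, cls) {
      purrr::imap_dfr(lst, function(m, i) {
        v <- mask_to_polygon(m)
        if (is.null(v)) return(NULL)
        tibble(class = cls, id = paste(cls, i),
               col = v[, 1] * (ncol(m) - 1) + 1,
               row = v[, 2] * (nrow(m) - 1) + 1)
      })
    })
    if (nrow(outline)) {
      p <- p + ggplot2::geom_path(
        data = outline,
        ggplot2::aes(group = .data$id, colour = .data$class),
        linewidth = 0.8) +
        ggplot2::scale_colour_manual(values = c(BAC = "#d55e00",
                                                AS = "#0072b2"))
    }
  }
  p
}

#' Plot per-plate solubilization efficiencies
#'
#' @param object a `plate_report`.
#' @param ... unused.
#' @return a ggplot object: Ef per plate, with the manual reference (when
#'   present) as open points.
#' @method autoplot plate_report
#' @export
autoplot.plate_report <- function(object, ...) {
  m <- object$measurements
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$plate, y = .data$ef)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = NULL, y = "solubilization efficiency Ef") +
    ggplot2::theme_minimal()
  if ("ef_manual" %in% names(m)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$ef_manual),
                                 shape = 1, size = 3, na.rm = TRUE)
  }
  p
}

#' Plot an evaluation metric table
#'
#' @param metrics output of [metrics_report()] in long (per-run) form.
#' @return a ggplot object faceted by metric.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(metrics,
                              c("precision", "recall", "f1", "accuracy"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "metric value (truncated)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
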