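#' Plot methods for gnrhkit results
#'
#' `autoplot()` methods returning ggplot objects: the TM3-TM6 activation
#' trace with rolling mean and baseline, the per-frame bridge state with its
#' smoothed occupancy, the PC1-PC2 projection, a KDE population surface, and
#' the RDF curve.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name gnrhkit-autoplot
NULL

#' @rdname gnrhkit-autoplot
#' @export
autoplot.activation_report <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$distance), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rolling_mean), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$baseline, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$baseline + object$threshold_delta,
                        linetype = "dotted") +
    ggplot2::labs(x = "frame", y = "TM3-TM6 distance (Å)")
  if (object$activated) {
    p <- p + ggplot2::geom_vline(xintercept = object$activation_frame,
                                 colour = "firebrick")
  }
  p
}

#' @rdname gnrhkit-autoplot
#' @param window Smoothing window (frames) for the occupancy overlay.
#' @export
autoplot.bridge_series <- function(object, window = 50, ...) {
  df <- tidy(object)
  df$smoothed <- smooth_series(df$bridged, min(window, nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_col(ggplot2::aes(y = as.numeric(.data$bridged)),
                      width = 1, fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$significance, linetype = "dotted") +
    ggplot2::labs(x = "frame", y = "bridge state / smoothed occupancy",
                  title = paste(object$pair, collapse = " – "))
}

#' @rdname gnrhkit-autoplot
#' @export
autoplot.pca_result <- function(object, ...) {
  ggplot2::ggplot(object$projection,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$frame)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_ratio[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_ratio[2])
    )
}

#' @rdname gnrhkit-autoplot
#' @export
autoplot.kde_surface <- function(object, ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$density <- as.vector(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "PC1", y = "PC2", fill = "density")
}

#' @rdname gnrhkit-autoplot
#' @export
autoplot.rdf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "r (Å)", y = "g(r)")
}
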