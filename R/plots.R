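# ggplot2 views of the main result types.

#' Display a hologram or normalized frame
#'
#' @param frame Numeric matrix.
#' @param detections Optional detection tibble whose boxes are overlaid.
#' @return A ggplot.
#' @export
plot_hologram <- function(frame, detections = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(frame)) - 1,
                           x = seq_len(ncol(frame)) - 1)
  df$intensity <- as.vector(t(frame))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "I")
  if (!is.null(detections) && nrow(detections) > 0) {
    d <- tibble::as_tibble(detections)
    p <- p + ggplot2::geom_rect(
      data = d,
      ggplot2::aes(xmin = .data$x_center - .data$width / 2,
                   xmax = .data$x_center + .data$width / 2,
                   ymin = .data$y_center - .data$height / 2,
                   ymax = .data$y_center + .data$height / 2),
      inherit.aes = FALSE, fill = NA, colour = "cyan", linetype = "dashed")
  }
  p
}

#' Plot 3D tracks as a lateral projection coloured by depth
#'
#' @param tracks Tibble from [link_tracks()] (or ground truth with a
#'   `track` column).
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks) {
  t <- tibble::as_tibble(tracks)
  ggplot2::ggplot(t, ggplot2::aes(.data$x_um, .data$y_um,
                                  group = .data$track,
                                  colour = .data$z_um)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "z (µm)")
}

#' @export
autoplot.heuristic_cal <- function(object, ...) {
  pr <- object$pairs
  p <- ggplot2::ggplot()
  if (!is.null(pr)) {
    p <- p + ggplot2::geom_point(data = pr,
                                 ggplot2::aes(.data$z, .data$size),
                                 colour = "grey40")
  }
  p +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$raw_intercept,
                         colour = "black") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "axial position z (µm)",
                  y = "bounding box side (px)",
                  title = "Box-size vs depth heuristic",
                  subtitle = "solid: regime fit; dashed: fit + vertical offset")
}

#' @export
autoplot.depth_correction <- function(object, pairs = NULL, ...) {
  g <- seq(object$domain[1], object$domain[2], length.out = 200)
  df <- tibble::tibble(z_raw = g,
                       z_corr = poly_eval(object$coefficients, g))
  p <- ggplot2::ggplot()
  if (!is.null(pairs)) {
    p <- p + ggplot2::geom_point(data = tibble::as_tibble(pairs),
                                 ggplot2::aes(.data$z_raw, .data$z_true),
                                 alpha = 0.4)
  }
  p +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(.data$z_raw, .data$z_corr),
                       colour = "red") +
    ggplot2::labs(x = "raw depth from box size (µm)",
                  y = "corrected depth (µm)",
                  title = "Fourth-order depth correction")
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$iou_threshold, .data$ap)) +
    ggplot2::geom_col(width = 0.035) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "IoU threshold", y = "average precision",
                  title = sprintf("mAP(0.5) = %.3f, mAP(0.5:0.95) = %.3f",
                                  object$map50, object$map50_95))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
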