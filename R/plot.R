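map_to_df <- function(grid, values, name = "value") {
  pc <- grid_pixel_centers(grid)
  df <- data.frame(x_mm = pc[, 1] * 1e3, y_mm = pc[, 2] * 1e3,
                   value = as.vector(values))
  names(df)[3] <- name
  df
}

#' Plot an SOS map
#'
#' ggplot2 raster display of a speed map in mm / (m/s) units.
#'
#' @param object an [sos_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sos_map <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- map_to_df(object$grid, object$values, "speed")
  ggplot2::ggplot(df, ggplot2::aes(x_mm, y_mm,
                                   fill = speed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "SOS (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Plot a reconstructed image
#'
#' @param object a [recon_image()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.recon_image <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- map_to_df(object$grid, object$values, "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(x_mm, y_mm,
                                   fill = amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "a.u.") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Plot the convergence trace of an inversion
#'
#' @param object a [solve_deficit()] result.
#' @param ... unused.
#' @return a ggplot object (log-scale objective vs iteration).
#' @exportS3Method ggplot2::autoplot
autoplot.slowness_deficit <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(iteration, objective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective")
}
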