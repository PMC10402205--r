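#' Plot a volume slice or projection
#'
#' @param object An `ulm_volume`.
#' @param slice Axial slice index, or `NULL` for the maximum-intensity
#'   projection along z.
#' @param trans Intensity transform: `"identity"`, `"sqrt"`, `"db"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ulm_volume <- function(object, slice = NULL, trans = "identity",
                                ...) {
  img <- if (is.null(slice)) mip(object, 3) else
    Mod(object$data[, , slice])
  xs <- grid_axis(object$grid, 1)
  ys <- grid_axis(object$grid, 2)
  df <- tibble::tibble(x = rep(xs, times = length(ys)),
                       y = rep(ys, each = length(xs)),
                       value = as.vector(img))
  df$value <- switch(trans,
                     sqrt = sqrt(df$value),
                     db = 20 * log10(pmax(df$value / max(df$value,
                                                         na.rm = TRUE),
                                          1e-6)),
                     df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = object$kind,
                  title = sprintf("%s %s", object$kind,
                                  if (is.null(slice)) "lateral MIP" else
                                    sprintf("slice z=%d", slice))) +
    ggplot2::theme_minimal()
}

#' Plot microbubble tracks
#'
#' Lateral (x, y) projection of all tracks coloured by instantaneous speed.
#'
#' @param object A `track_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.track_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$track_id,
                                   colour = .data$speed)) +
    ggplot2::geom_path(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::scale_colour_viridis_c(option = "plasma", na.value = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "speed (mm/s)") +
    ggplot2::theme_minimal()
}

#' Plot per-hemisphere vessel parameter distributions
#'
#' @param vessels A `vessel_set` with hemispheres assigned.
#' @param parameter Column to compare.
#' @return A ggplot object.
#' @export
plot_vessel_stats <- function(vessels, parameter = "mean_speed_mms") {
  df <- tidy.vessel_set(vessels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[parameter]],
                                   fill = .data$hemisphere)) +
    ggplot2::geom_density(alpha = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = parameter, y = "density") +
    ggplot2::theme_minimal()
}
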