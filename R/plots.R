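#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibrated image
#'
#' @param image A [fiber_image()] (or a [discretize_fibers()] blueprint,
#'   whose graded map is shown).
#' @param trans Intensity transform: `"identity"` or `"sqrt"` (default,
#'   compresses bright fiber cores).
#' @return A ggplot.
#' @export
plot_fiber_image <- function(image, trans = c("sqrt", "identity")) {
  trans <- match.arg(trans)
  if (inherits(image, "blueprint")) {
    image <- fiber_image(image$graded, image$pixel_size_um)
  }
  m <- image$pixels
  px <- image$pixel_size_um
  df <- tidyr::expand_grid(
    y_um = (seq_len(nrow(m)) - 0.5) * px,
    x_um = (seq_len(ncol(m)) - 0.5) * px
  )
  df$intensity <- as.vector(t(m))
  if (trans == "sqrt") df$intensity <- sqrt(df$intensity)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot cell trajectories (origin-aligned rose of tracks)
#'
#' @param tracks Trajectory tibble.
#' @param align_origin Subtract each track's starting point (default TRUE),
#'   the usual wind-rose view of migration data.
#' @return A ggplot.
#' @export
plot_trajectories <- function(tracks, align_origin = TRUE) {
  check_trajectories(tracks)
  df <- tracks |>
    dplyr::arrange(.data$track_id, .data$t_min)
  if (align_origin) {
    df <- df |>
      dplyr::group_by(.data$track_id) |>
      dplyr::mutate(x_um = .data$x_um - dplyr::first(.data$x_um),
                    y_um = .data$y_um - dplyr::first(.data$y_um)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   group = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot-matricell MSD curve with the fitted Furth model
#'   overlaid when available.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_min, .data$msd_um2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' Autoplot methods for analysis results
#'
#' `autoplot()` turns the package's result objects into ggplots: MSD
#' curves, persistent-random-walk fits (data plus fitted Furth curve), and
#' angular distributions (axial orientation histograms).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-matricell
NULL

#' @describeIn autoplot-matricell PRW fit: observed MSD and the fitted
#'   Furth curve.
#' @export
autoplot.prw_fit <- function(object, ...) {
  curve <- object$curve
  pred <- tibble::tibble(
    lag_min = seq(min(curve$lag_min), max(curve$lag_min), length.out = 200)
  )
  pred$msd_um2 <- prw_msd(pred$lag_min, object$mu_um2_per_min, object$P_min,
                          object$n_d)
  ggplot2::ggplot(curve, ggplot2::aes(.data$lag_min, .data$msd_um2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = pred, color = "#B2182B") +
    ggplot2::labs(
      x = "lag (min)", y = expression(MSD ~ (mu * m^2)),
      subtitle = sprintf("mu = %.3g µm²/min, P = %.3g min",
                         object$mu_um2_per_min, object$P_min)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot-matricell Angular distribution as a bar histogram
#'   over `[0, 180)`.
#' @export
autoplot.angular_distribution <- function(object, ...) {
  df <- tidy.angular_distribution(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_mid_deg, .data$density)) +
    ggplot2::geom_col(width = diff(object$bin_edges_deg)[1],
                      fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = seq(0, 180, 45), limits = c(0, 180)) +
    ggplot2::labs(x = "orientation (deg)", y = "density") +
    ggplot2::theme_minimal()
}
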