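# ggplot2 graphics for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

image_raster_plot <- function(image, grid, title, fill_lab = "intensity") {
  co <- grid_coords(grid)
  df <- data.frame(
    x_nm = rep(co$x, each = length(co$y)),
    y_nm = rep(co$y, times = length(co$x)),
    value = as.vector(image)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = fill_lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a reconstruction result
#'
#' @param object A `recon_result`.
#' @param ... Unused.
#' @return A ggplot object (raster of the SR image in physical coordinates).
#' @exportS3Method ggplot2::autoplot
autoplot.recon_result <- function(object, ...) {
  image_raster_plot(object$sr_image, object$grid,
                    sprintf("%s reconstruction", object$method))
}

#' Plot an effective PSF
#'
#' @param object An `effective_psf` from [effective_psf()].
#' @param ... Unused.
#' @return A ggplot raster of the (unnormalized) effective PSF.
#' @exportS3Method ggplot2::autoplot
autoplot.effective_psf <- function(object, ...) {
  image_raster_plot(object$values, object$grid, "effective PSF", "P(r)")
}

#' Plot an effective-PSF FWHM curve
#'
#' @param object A `psf_fwhm_curve` tibble from [psf_fwhm_curve()].
#' @param ... Unused.
#' @return A ggplot of FWHM versus illumination period.
#' @exportS3Method ggplot2::autoplot
autoplot.psf_fwhm_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$period_nm, y = .data$fwhm_nm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "illumination period T (nm)",
                  y = "effective-PSF FWHM (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a bead FWHM report
#'
#' @param object An `fwhm_report` from [bead_fwhm_report()].
#' @param binwidth Histogram bin width in nanometres.
#' @param ... Unused.
#' @return A ggplot histogram of per-bead fitted FWHMs with the mean marked.
#' @exportS3Method ggplot2::autoplot
autoplot.fwhm_report <- function(object, binwidth = 5, ...) {
  ggplot2::ggplot(object$per_bead, ggplot2::aes(x = .data$fwhm_nm)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_fwhm_nm,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "fitted bead FWHM (nm)", y = "beads") +
    ggplot2::theme_minimal()
}

#' Intensity profile plot between two points
#'
#' Convenience wrapper around [profile_line()] for the classic two-point
#' resolvability figure.
#'
#' @param image Numeric matrix on `grid`.
#' @param grid A [grid2d()].
#' @param p0_nm,p1_nm Physical endpoints `c(x, y)` in nanometres.
#' @return A ggplot of intensity versus distance along the line.
#' @export
plot_profile <- function(image, grid, p0_nm, p1_nm) {
  pr <- profile_line(image, grid, p0_nm, p1_nm)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$t_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance along profile (nm)", y = "intensity") +
    ggplot2::theme_minimal()
}
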