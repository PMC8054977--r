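# Broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bead FWHM report
#'
#' @param x An `fwhm_report` from [bead_fwhm_report()].
#' @param ... Unused.
#' @return The per-bead tibble (`x_nm`, `y_nm`, `fwhm_nm`, `fit_residual`).
#' @exportS3Method generics::tidy
tidy.fwhm_report <- function(x, ...) x$per_bead

#' One-row summary of a bead FWHM report
#'
#' @inheritParams tidy.fwhm_report
#' @return Tibble with `n_beads`, `mean_fwhm_nm`, `sd_fwhm_nm`, `n_excluded`.
#' @exportS3Method generics::glance
glance.fwhm_report <- function(x, ...) {
  tibble::tibble(n_beads = x$n_beads,
                 mean_fwhm_nm = x$mean_fwhm_nm,
                 sd_fwhm_nm = x$sd_fwhm_nm,
                 n_excluded = nrow(x$excluded))
}

#' Pixel-level tibble of a reconstruction
#'
#' @param x A `recon_result`.
#' @param ... Unused.
#' @return Tibble with physical coordinates `x_nm`, `y_nm` and `value`.
#' @exportS3Method generics::tidy
tidy.recon_result <- function(x, ...) {
  co <- grid_coords(x$grid)
  tibble::tibble(
    x_nm = rep(co$x, each = length(co$y)),
    y_nm = rep(co$y, times = length(co$x)),
    value = as.vector(x$sr_image)
  )
}

#' One-row summary of a reconstruction
#'
#' @inheritParams tidy.recon_result
#' @return Tibble with the method, image size, pixel size, Wiener constant
#'   and intensity range.
#' @exportS3Method generics::glance
glance.recon_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_rows = nrow(x$sr_image),
    n_cols = ncol(x$sr_image),
    pixel_size_nm = if (!is.null(x$grid)) x$grid$pixel_size_nm else NA_real_,
    wiener_w = if (is.null(x$params$wiener_w)) NA_real_ else x$params$wiener_w,
    min = min(x$sr_image),
    max = max(x$sr_image)
  )
}
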