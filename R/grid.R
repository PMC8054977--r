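#' Pixel raster with physical pixel size
#'
#' The coordinate frame shared by all images in a reconstruction. Pixel
#' centers carry the physical coordinates; the origin is the geometric center
#' pixel at (zero-based) index `(floor(n_rows/2), floor(n_cols/2))`, so pixel
#' `(i, j)` sits at `((j - j0) * pixel_size_nm, (i - i0) * pixel_size_nm)`
#' with x rightward and y downward.
#'
#' @param n_rows,n_cols Pixel counts (each at least 8).
#' @param pixel_size_nm Physical size of one pixel in nanometres.
#' @return A `grid2d` object.
#' @examples
#' g <- grid2d(64, 64, 32.5)
#' range(grid_coords(g)$x)
#' @export
grid2d <- function(n_rows, n_cols = n_rows, pixel_size_nm = 32.5) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 8L || n_cols < 8L) {
    stop_sdrsim("grid must be at least 8 x 8 pixels", "sdrsim_invalid_parameter")
  }
  check_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_size_nm = pixel_size_nm),
    class = "grid2d"
  )
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d pixels, %.4g nm/pixel (%.3g x %.3g um)\n",
              x$n_rows, x$n_cols, x$pixel_size_nm,
              x$n_cols * x$pixel_size_nm / 1e3,
              x$n_rows * x$pixel_size_nm / 1e3))
  invisible(x)
}

#' Physical pixel-center coordinates of a grid
#'
#' @param grid A [grid2d()].
#' @return List with numeric vectors `x` (length `n_cols`) and `y` (length
#'   `n_rows`) in nanometres, zero at the origin pixel.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid2d"))
  j0 <- grid$n_cols %/% 2L
  i0 <- grid$n_rows %/% 2L
  list(
    x = (seq_len(grid$n_cols) - 1L - j0) * grid$pixel_size_nm,
    y = (seq_len(grid$n_rows) - 1L - i0) * grid$pixel_size_nm
  )
}

# 1-based index of the origin pixel.
grid_origin_index <- function(grid) {
  c(i = grid$n_rows %/% 2L + 1L, j = grid$n_cols %/% 2L + 1L)
}

# Phase field 2*pi*(k . r) for wavevector k in cycles/nm; returns a matrix.
grid_phase <- function(grid, k) {
  co <- grid_coords(grid)
  outer(2 * pi * k[2] * co$y, 2 * pi * k[1] * co$x, `+`)
}

grids_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$pixel_size_nm, b$pixel_size_nm))
}
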