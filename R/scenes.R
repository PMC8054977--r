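# Synthetic ground-truth objects: sparse bead fields, two-point separation
# targets, bar/line targets, uniform fields, and single point sources. Each
# scene records an exact structured truth alongside its fluorophore-density
# image.

new_scene_object <- function(image, truth, grid) {
  stopifnot(is.matrix(image), all(is.finite(image)), all(image >= 0))
  structure(list(image = image, truth = truth, grid = grid),
            class = "scene_object")
}

#' @export
print.scene_object <- function(x, ...) {
  cat(sprintf("<scene_object> kind '%s' on %d x %d grid\n",
              x$truth$kind, x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

# Add a round Gaussian emitter of given FWHM at an exact (possibly subpixel)
# physical position; rendered only within +/- 6 sigma for speed.
add_gaussian_spot <- function(image, grid, cx_nm, cy_nm, fwhm_nm, amplitude) {
  co <- grid_coords(grid)
  sigma <- fwhm_nm * FWHM_TO_SIGMA
  reach <- 6 * sigma
  jj <- which(abs(co$x - cx_nm) <= reach)
  ii <- which(abs(co$y - cy_nm) <= reach)
  if (length(ii) == 0L || length(jj) == 0L) return(image)
  gx <- exp(-(co$x[jj] - cx_nm)^2 / (2 * sigma^2))
  gy <- exp(-(co$y[ii] - cy_nm)^2 / (2 * sigma^2))
  image[ii, jj] <- image[ii, jj] + amplitude * outer(gy, gx)
  image
}

#' Random field of sub-diffraction fluorescent beads
#'
#' Places `n_beads` bead emitters uniformly at random inside the grid (keeping
#' a border margin so periodic-boundary convolution cannot wrap bead signal)
#' while enforcing a minimum pairwise separation by rejection sampling. Beads
#' are rendered as Gaussian spots whose FWHM equals the bead diameter, i.e.
#' effectively point-like relative to a 200 nm detection PSF.
#'
#' @param grid A [grid2d()].
#' @param n_beads Number of beads (>= 1).
#' @param min_separation_nm Minimum center-to-center distance in nanometres.
#' @param seed Integer seed; identical seeds give identical scenes.
#' @param bead_diameter_nm Bead diameter, default 40 nm.
#' @param amplitude Emitter amplitude (density peak) per bead; default 25
#'   puts noise-free raw-frame peaks near 1000 counts with the default
#'   patterns and a 200 nm PSF.
#' @param margin_nm Exclusion border; default 600 nm (3 x a 200 nm PSF FWHM).
#' @param max_attempts Rejection-sampling budget before a packing error.
#' @return A `scene_object`; `truth` lists `kind = "beads"`, exact centers
#'   (`x_nm`, `y_nm`), amplitudes, and the diameter.
#' @export
make_bead_field <- function(grid, n_beads, min_separation_nm = 500, seed = 1L,
                            bead_diameter_nm = 40, amplitude = 25,
                            margin_nm = 600, max_attempts = 1000L * n_beads) {
  stopifnot(inherits(grid, "grid2d"))
  n_beads <- as.integer(n_beads)
  if (is.na(n_beads) || n_beads < 1L) {
    stop_sdrsim("n_beads must be >= 1", "sdrsim_invalid_parameter")
  }
  check_number(min_separation_nm, "min_separation_nm", nonnegative = TRUE)
  check_number(bead_diameter_nm, "bead_diameter_nm", positive = TRUE)
  co <- grid_coords(grid)
  xr <- c(min(co$x) + margin_nm, max(co$x) - margin_nm)
  yr <- c(min(co$y) + margin_nm, max(co$y) - margin_nm)
  if (diff(xr) <= 0 || diff(yr) <= 0) {
    stop_sdrsim("grid too small for the requested border margin",
                "sdrsim_invalid_parameter")
  }
  centers <- with_local_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    while (length(xs) < n_beads) {
      if (attempts >= max_attempts) {
        stop_sdrsim(sprintf(
          "could not place %d beads at min separation %g nm after %d attempts",
          n_beads, min_separation_nm, attempts), "sdrsim_packing_error")
      }
      attempts <- attempts + 1L
      cx <- stats::runif(1, xr[1], xr[2])
      cy <- stats::runif(1, yr[1], yr[2])
      if (length(xs) == 0L ||
          all((xs - cx)^2 + (ys - cy)^2 >= min_separation_nm^2)) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    list(x = xs, y = ys)
  })
  img <- matrix(0, grid$n_rows, grid$n_cols)
  for (b in seq_len(n_beads)) {
    img <- add_gaussian_spot(img, grid, centers$x[b], centers$y[b],
                             bead_diameter_nm, amplitude)
  }
  new_scene_object(
    img,
    list(kind = "beads",
         x_nm = centers$x, y_nm = centers$y,
         amplitude = rep(amplitude, n_beads),
         bead_diameter_nm = bead_diameter_nm, seed = seed),
    grid
  )
}

#' Two-point separation target
#'
#' Two equal point emitters centered on the grid, separated by
#' `separation_nm` along `axis_deg`. Emitters land on the nearest pixel when
#' the geometry is pixel-aligned, otherwise they are rendered as one-pixel
#' FWHM Gaussian spots at the exact subpixel positions.
#'
#' @param grid A [grid2d()].
#' @param separation_nm Center-to-center distance (>= one pixel).
#' @param axis_deg Orientation of the separation axis from +x, degrees.
#' @param amplitude Emitter amplitude.
#' @return A `scene_object` with `truth$kind = "two_point"` and the two exact
#'   centers.
#' @export
make_two_point <- function(grid, separation_nm, axis_deg = 0, amplitude = 25) {
  stopifnot(inherits(grid, "grid2d"))
  check_number(separation_nm, "separation_nm", positive = TRUE)
  px <- grid$pixel_size_nm
  if (separation_nm < px) {
    stop_sdrsim("separation below one pixel cannot be represented",
                "sdrsim_invalid_parameter")
  }
  th <- axis_deg * pi / 180
  half <- separation_nm / 2
  cx <- c(-half * cos(th), half * cos(th))
  cy <- c(-half * sin(th), half * sin(th))
  co <- grid_coords(grid)
  if (any(cx < min(co$x)) || any(cx > max(co$x)) ||
      any(cy < min(co$y)) || any(cy > max(co$y))) {
    stop_sdrsim("emitters fall outside the grid", "sdrsim_invalid_parameter")
  }
  img <- matrix(0, grid$n_rows, grid$n_cols)
  org <- grid_origin_index(grid)
  for (p in 1:2) {
    jf <- cx[p] / px; if_ <- cy[p] / px
    if (max(abs(jf - round(jf)), abs(if_ - round(if_))) < 1e-9) {
      img[org["i"] + round(if_), org["j"] + round(jf)] <-
        img[org["i"] + round(if_), org["j"] + round(jf)] + amplitude
    } else {
      img <- add_gaussian_spot(img, grid, cx[p], cy[p], px, amplitude)
    }
  }
  new_scene_object(
    img,
    list(kind = "two_point", x_nm = cx, y_nm = cy,
         amplitude = rep(amplitude, 2), separation_nm = separation_nm,
         axis_deg = axis_deg),
    grid
  )
}

#' Single point source at the grid origin
#'
#' A delta emitter at the origin pixel; the canonical probe of the effective
#' PSF of a reconstruction.
#'
#' @param grid A [grid2d()].
#' @param amplitude Emitter amplitude.
#' @return A `scene_object` with `truth$kind = "point"`.
#' @export
make_point_source <- function(grid, amplitude = 25) {
  stopifnot(inherits(grid, "grid2d"))
  img <- matrix(0, grid$n_rows, grid$n_cols)
  org <- grid_origin_index(grid)
  img[org["i"], org["j"]] <- amplitude
  new_scene_object(
    img, list(kind = "point", x_nm = 0, y_nm = 0, amplitude = amplitude), grid
  )
}

#' Bar (line-pair) resolution target
#'
#' Alternating bright/dark bars at 50% duty cycle, analogous to one group of a
#' USAF resolution chart. The pattern covers `n_bars` full periods across the
#' bar axis, centered on the grid.
#'
#' @param grid A [grid2d()].
#' @param bar_period_nm Bright + dark period, at least two pixels.
#' @param n_bars Number of bright bars (>= 1).
#' @param orientation_deg Direction across the bars (normal to the bar edges).
#' @param bar_length_nm Bar length; default `n_bars * bar_period_nm`.
#' @param amplitude Bright-bar density value.
#' @return A `scene_object` with `truth$kind = "bars"` and the geometry.
#' @export
make_bar_target <- function(grid, bar_period_nm, n_bars = 3L,
                            orientation_deg = 0, bar_length_nm = NULL,
                            amplitude = 25) {
  stopifnot(inherits(grid, "grid2d"))
  check_number(bar_period_nm, "bar_period_nm", positive = TRUE)
  if (bar_period_nm < 2 * grid$pixel_size_nm) {
    stop_sdrsim("bar period below two pixels cannot be represented",
                "sdrsim_invalid_parameter")
  }
  n_bars <- as.integer(n_bars)
  if (is.na(n_bars) || n_bars < 1L) {
    stop_sdrsim("n_bars must be >= 1", "sdrsim_invalid_parameter")
  }
  if (is.null(bar_length_nm)) bar_length_nm <- n_bars * bar_period_nm
  th <- orientation_deg * pi / 180
  co <- grid_coords(grid)
  X <- matrix(co$x, grid$n_rows, grid$n_cols, byrow = TRUE)
  Y <- matrix(co$y, grid$n_rows, grid$n_cols)
  u <- X * cos(th) + Y * sin(th)        # across the bars
  v <- -X * sin(th) + Y * cos(th)       # along the bars
  W <- n_bars * bar_period_nm
  on <- (u >= -W / 2) & (u < W / 2) &
    (((u + W / 2) %% bar_period_nm) < bar_period_nm / 2) &
    (abs(v) <= bar_length_nm / 2)
  img <- matrix(0, grid$n_rows, grid$n_cols)
  img[on] <- amplitude
  new_scene_object(
    img,
    list(kind = "bars", bar_period_nm = bar_period_nm, n_bars = n_bars,
         orientation_deg = orientation_deg, bar_length_nm = bar_length_nm,
         amplitude = amplitude),
    grid
  )
}

#' Uniform fluorophore field
#'
#' Constant density over the whole grid; with periodic-boundary convolution
#' the raw frames of a uniform object carry a pure sinusoidal modulation whose
#' contrast is the pattern contrast attenuated by the OTF at the pattern
#' frequency.
#'
#' @param grid A [grid2d()].
#' @param value Constant density value.
#' @return A `scene_object` with `truth$kind = "uniform"`.
#' @export
make_uniform_field <- function(grid, value = 25) {
  stopifnot(inherits(grid, "grid2d"))
  check_number(value, "value", nonnegative = TRUE)
  new_scene_object(
    matrix(value, grid$n_rows, grid$n_cols),
    list(kind = "uniform", value = value),
    grid
  )
}
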