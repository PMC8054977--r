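# Physical optics models: Gaussian detection PSF, sinusoidal illumination,
# the compressed effective PSF of the superposition image, and transfer
# functions.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Gaussian point spread function
#'
#' The widefield detection PSF is modeled as an isotropic Gaussian
#' `H(r) = exp(-|r|^2 / (2 sigma^2))` with `sigma = fwhm_nm / (2 sqrt(2 ln 2))`
#' and peak value 1 at the origin. The conventional diffraction-limited value
#' for a high-NA visible-light system is a FWHM near 200 nm.
#'
#' @param fwhm_nm Full width at half maximum in nanometres (> 0).
#' @return A `gaussian_psf` object with fields `fwhm_nm` and `sigma_nm`.
#' @examples
#' h <- gaussian_psf(200)
#' h$sigma_nm
#' @export
gaussian_psf <- function(fwhm_nm = 200) {
  check_number(fwhm_nm, "fwhm_nm", positive = TRUE)
  structure(
    list(fwhm_nm = fwhm_nm, sigma_nm = fwhm_nm * FWHM_TO_SIGMA),
    class = "gaussian_psf"
  )
}

#' @export
print.gaussian_psf <- function(x, ...) {
  cat(sprintf("<gaussian_psf> FWHM %.4g nm (sigma %.4g nm)\n", x$fwhm_nm, x$sigma_nm))
  invisible(x)
}

#' Render a Gaussian PSF on a pixel grid
#'
#' Peak-normalized (value 1 at the origin pixel), radially symmetric up to the
#' grid discretization. Warns when the grid is too small for the PSF to decay
#' below 1e-6 of its peak at the border, since FFT convolution then wraps
#' non-negligible tails.
#'
#' @param psf A [gaussian_psf()].
#' @param grid A [grid2d()].
#' @return Numeric matrix of dimension `n_rows x n_cols`.
#' @export
gaussian_psf_image <- function(psf, grid) {
  stopifnot(inherits(psf, "gaussian_psf"), inherits(grid, "grid2d"))
  co <- grid_coords(grid)
  gx <- exp(-co$x^2 / (2 * psf$sigma_nm^2))
  gy <- exp(-co$y^2 / (2 * psf$sigma_nm^2))
  img <- outer(gy, gx)
  border_max <- max(img[1, ], img[grid$n_rows, ], img[, 1], img[, grid$n_cols])
  if (border_max > 1e-6) {
    warning(sprintf(
      "PSF does not decay below 1e-6 of peak at the grid border (%.3g); enlarge the grid",
      border_max))
  }
  img
}

#' Sinusoidal illumination pattern parameters
#'
#' One orientation of the structured illumination field
#' `I(r) = I0 * (1 + m cos(2 pi k . r + phi0 - psi_j))`, where `k` is the
#' pattern wavevector of magnitude `1/period_nm` along `orientation_deg` and
#' `psi_j` is the fringe phase shift of raw frame `j`. The canonical
#' three-step acquisition uses shifts of 0 and -/+ 120 degrees.
#'
#' @param period_nm Fringe period `T = 1/k0` in nanometres (> 0).
#' @param orientation_deg Angle of the wavevector from the +x axis, degrees.
#' @param modulation_depth Fringe contrast `m` in (0, 1].
#' @param mean_intensity Mean illumination intensity `I0` (> 0), photon-rate
#'   units.
#' @param initial_phase_rad Fringe phase `phi0` at the grid origin, radians.
#' @param phase_shifts_rad Ordered phase shifts `psi_j`, distinct modulo 2 pi.
#' @return A `sinusoid_pattern` object.
#' @examples
#' sinusoid_pattern(220, orientation_deg = 60)
#' @export
sinusoid_pattern <- function(period_nm,
                             orientation_deg = 0,
                             modulation_depth = 0.9,
                             mean_intensity = 1,
                             initial_phase_rad = 0,
                             phase_shifts_rad = c(0, -2 * pi / 3, 2 * pi / 3)) {
  check_number(period_nm, "period_nm", positive = TRUE)
  check_number(orientation_deg, "orientation_deg")
  check_number(modulation_depth, "modulation_depth", positive = TRUE)
  if (modulation_depth > 1) {
    stop_sdrsim("modulation_depth must lie in (0, 1]", "sdrsim_invalid_parameter")
  }
  check_number(mean_intensity, "mean_intensity", positive = TRUE)
  check_number(initial_phase_rad, "initial_phase_rad")
  if (!is.numeric(phase_shifts_rad) || length(phase_shifts_rad) < 1L) {
    stop_sdrsim("phase_shifts_rad must be a nonempty numeric vector",
                "sdrsim_invalid_parameter")
  }
  wrapped <- phase_shifts_rad %% (2 * pi)
  if (anyDuplicated(round(wrapped, 12)) > 0L) {
    stop_sdrsim("phase shifts must be distinct modulo 2*pi",
                "sdrsim_invalid_parameter")
  }
  structure(
    list(period_nm = period_nm,
         orientation_deg = orientation_deg,
         modulation_depth = modulation_depth,
         mean_intensity = mean_intensity,
         initial_phase_rad = initial_phase_rad,
         phase_shifts_rad = as.numeric(phase_shifts_rad)),
    class = "sinusoid_pattern"
  )
}

#' @export
print.sinusoid_pattern <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_pattern> T = %.4g nm @ %.4g deg, m = %.3g, I0 = %.4g, phi0 = %.3g rad, %d phases\n",
    x$period_nm, x$orientation_deg, x$modulation_depth, x$mean_intensity,
    x$initial_phase_rad, length(x$phase_shifts_rad)))
  invisible(x)
}

#' Pattern wavevector in cycles per nanometre
#'
#' @param pattern A [sinusoid_pattern()].
#' @return Numeric length-2 vector `(kx, ky)` of magnitude `1/period_nm`.
#' @export
pattern_wavevector <- function(pattern) {
  stopifnot(inherits(pattern, "sinusoid_pattern"))
  th <- pattern$orientation_deg * pi / 180
  c(cos(th), sin(th)) / pattern$period_nm
}

#' Render one phase-shifted illumination frame
#'
#' Evaluates `I0 * (1 + m cos(2 pi k . r + phi0 - psi_j))` on the grid for the
#' requested phase step.
#'
#' @param pattern A [sinusoid_pattern()].
#' @param shift_index 1-based index into `phase_shifts_rad`.
#' @param grid A [grid2d()].
#' @return Numeric matrix with values in `[I0 (1 - m), I0 (1 + m)]`.
#' @export
illumination_image <- function(pattern, shift_index, grid) {
  stopifnot(inherits(pattern, "sinusoid_pattern"), inherits(grid, "grid2d"))
  shift_index <- as.integer(shift_index)
  if (is.na(shift_index) || shift_index < 1L ||
      shift_index > length(pattern$phase_shifts_rad)) {
    stop_sdrsim(sprintf("shift_index %d out of range 1..%d", shift_index,
                        length(pattern$phase_shifts_rad)),
                "sdrsim_index_error")
  }
  ph <- grid_phase(grid, pattern_wavevector(pattern)) +
    pattern$initial_phase_rad - pattern$phase_shifts_rad[shift_index]
  pattern$mean_intensity * (1 + pattern$modulation_depth * cos(ph))
}

#' Effective (compressed) PSF of the spatial-domain superposition
#'
#' For a single orientation the superposition image of a point source is
#' governed by `P(r) = (1 + cos(2 pi k . r)) H(r)` - the detection PSF
#' modulated by the cosine target function, narrower than `H` along the
#' pattern axis. For several orientations the per-orientation superpositions
#' add, so the combined effective PSF is the sum of the per-orientation terms
#' (unnormalized).
#'
#' @param psf A [gaussian_psf()].
#' @param patterns A single [sinusoid_pattern()] or a list of them.
#' @param grid A [grid2d()].
#' @return An `effective_psf` object: `values` (matrix), `grid`, `source_psf`,
#'   `patterns`.
#' @export
effective_psf <- function(psf, patterns, grid) {
  stopifnot(inherits(psf, "gaussian_psf"), inherits(grid, "grid2d"))
  if (inherits(patterns, "sinusoid_pattern")) patterns <- list(patterns)
  if (length(patterns) < 1L) {
    stop_sdrsim("at least one illumination pattern is required",
                "sdrsim_invalid_parameter")
  }
  stopifnot(all(vapply(patterns, inherits, logical(1), "sinusoid_pattern")))
  H <- gaussian_psf_image(psf, grid)
  values <- matrix(0, grid$n_rows, grid$n_cols)
  for (p in patterns) {
    values <- values + (1 + cos(grid_phase(grid, pattern_wavevector(p)))) * H
  }
  structure(
    list(values = values, grid = grid, source_psf = psf, patterns = patterns),
    class = "effective_psf"
  )
}

#' @export
print.effective_psf <- function(x, ...) {
  cat(sprintf("<effective_psf> %d orientation(s) on %d x %d grid, peak %.4g\n",
              length(x$patterns), x$grid$n_rows, x$grid$n_cols, max(x$values)))
  invisible(x)
}

#' 1-D effective-PSF profile along the modulation axis
#'
#' Fine 1-D sampling of `P(x) = (1 + cos(2 pi x / T)) H(x)` used for FWHM
#' analysis; independent of any pixel raster.
#'
#' @param psf A [gaussian_psf()].
#' @param period_nm Illumination period in nanometres.
#' @param spacing_nm Sample spacing (default 0.1 nm).
#' @param half_range_nm Profile extends over +/- this range (default 1000 nm).
#' @return A tibble with columns `x_nm` and `value`.
#' @export
effective_psf_profile <- function(psf, period_nm, spacing_nm = 0.1,
                                  half_range_nm = 1000) {
  stopifnot(inherits(psf, "gaussian_psf"))
  check_number(period_nm, "period_nm", positive = TRUE)
  check_number(spacing_nm, "spacing_nm", positive = TRUE)
  x <- seq(-half_range_nm, half_range_nm, by = spacing_nm)
  v <- (1 + cos(2 * pi * x / period_nm)) * exp(-x^2 / (2 * psf$sigma_nm^2))
  tibble::tibble(x_nm = x, value = v)
}

#' Full width at half maximum of a sampled peak
#'
#' Walks outward from the global maximum to the first half-maximum crossings
#' on either side and interpolates them linearly. Model-free; suited to
#' non-Gaussian peaks such as the cosine-modulated effective PSF.
#'
#' @param values Numeric vector with a single dominant central peak.
#' @param spacing Physical distance between consecutive samples.
#' @return FWHM in the units of `spacing`.
#' @export
fwhm_halfmax <- function(values, spacing) {
  check_number(spacing, "spacing", positive = TRUE)
  if (length(values) < 3L || !all(is.finite(values))) {
    stop_sdrsim("need at least 3 finite samples", "sdrsim_invalid_parameter")
  }
  i_max <- which.max(values)
  if (i_max == 1L || i_max == length(values)) {
    stop_sdrsim("profile maximum lies on the boundary; no central peak",
                "sdrsim_invalid_parameter")
  }
  half <- values[i_max] / 2
  cross <- function(idx_seq) {
    for (i in idx_seq) {
      if (values[i] < half) {
        # linear interpolation between i and the previous sample toward peak
        prev <- if (i < i_max) i + 1L else i - 1L
        frac <- (values[prev] - half) / (values[prev] - values[i])
        return(abs(prev - i_max) + frac)
      }
    }
    stop_sdrsim("peak does not fall below half maximum within the profile",
                "sdrsim_invalid_parameter")
  }
  left <- cross(seq(i_max - 1L, 1L))
  right <- cross(seq(i_max + 1L, length(values)))
  (left + right) * spacing
}

#' Effective-PSF FWHM as a function of the illumination period
#'
#' Sweeps the fringe period and measures the along-axis FWHM of the effective
#' PSF on a fine 1-D profile. The FWHM shrinks as the period approaches the
#' diffraction-limited minimum and recovers the widefield value as the period
#' grows toward uniform illumination.
#'
#' @inheritParams effective_psf_profile
#' @param periods_nm Vector of fringe periods in nanometres (> 0).
#' @return A tibble (class `psf_fwhm_curve`) with columns `period_nm`,
#'   `fwhm_nm`.
#' @examples
#' psf_fwhm_curve(gaussian_psf(200), c(200, 400, 1e6))
#' @export
psf_fwhm_curve <- function(psf, periods_nm, spacing_nm = 0.1,
                           half_range_nm = 1000) {
  stopifnot(inherits(psf, "gaussian_psf"))
  if (!is.numeric(periods_nm) || length(periods_nm) < 1L || any(periods_nm <= 0)) {
    stop_sdrsim("periods_nm must be positive", "sdrsim_invalid_parameter")
  }
  fwhm <- vapply(periods_nm, function(T) {
    pr <- effective_psf_profile(psf, T, spacing_nm, half_range_nm)
    fwhm_halfmax(pr$value, spacing_nm)
  }, numeric(1))
  out <- tibble::tibble(period_nm = as.numeric(periods_nm), fwhm_nm = fwhm)
  class(out) <- c("psf_fwhm_curve", class(out))
  out
}

#' Optical transfer function from a sampled PSF
#'
#' Discrete Fourier transform of the origin-centered PSF, normalized to value
#' 1 at zero frequency. Conjugate-symmetric (real for symmetric PSFs).
#'
#' @param psf_image Nonnegative, finite numeric matrix with its peak at the
#'   grid origin pixel.
#' @return Complex matrix in standard DFT (wrap-around) frequency order.
#' @export
otf_from_psf <- function(psf_image) {
  if (!is.matrix(psf_image) || !all(is.finite(psf_image)) || any(psf_image < 0)) {
    stop_sdrsim("psf_image must be a finite nonnegative matrix",
                "sdrsim_invalid_parameter")
  }
  s <- sum(psf_image)
  if (s == 0) {
    stop_sdrsim("psf_image is identically zero", "sdrsim_invalid_parameter")
  }
  fft2(ifftshift2(psf_image)) / s
}
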