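# Forward simulator: raw SIM frames are the object times the phase-shifted
# illumination, blurred by the detection PSF (FFT convolution, periodic
# boundaries), with optional seeded Poisson shot noise and Gaussian read
# noise.

#' Camera noise model
#'
#' @param poisson Apply Poisson shot noise to each pixel's expected count.
#' @param read_noise_sd Standard deviation of additive Gaussian read noise in
#'   counts (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical noise.
#' @return A `noise_model` object.
#' @export
noise_model <- function(poisson = TRUE, read_noise_sd = 2, seed = 1L) {
  stopifnot(is.logical(poisson), length(poisson) == 1L)
  check_number(read_noise_sd, "read_noise_sd", nonnegative = TRUE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop_sdrsim("seed must be an integer", "sdrsim_invalid_parameter")
  structure(list(poisson = poisson, read_noise_sd = read_noise_sd, seed = seed),
            class = "noise_model")
}

#' Snap a pattern's wavevector to the spectral pixel raster
#'
#' Rounds each wavevector component to an integer multiple of one frequency
#' pixel (`1 / (n_pixels * pixel_size)` per axis) so that the frequency-domain
#' pipeline can translate spectral bands by whole pixels with no
#' interpolation. The period and orientation change by at most one spectral
#' pixel.
#'
#' @param pattern A [sinusoid_pattern()].
#' @param grid The acquisition [grid2d()].
#' @return A `sinusoid_pattern` with adjusted `period_nm`/`orientation_deg`.
#' @export
snap_pattern_to_grid <- function(pattern, grid) {
  stopifnot(inherits(pattern, "sinusoid_pattern"), inherits(grid, "grid2d"))
  k <- pattern_wavevector(pattern)
  fov_x <- grid$n_cols * grid$pixel_size_nm
  fov_y <- grid$n_rows * grid$pixel_size_nm
  kp <- c(round(k[1] * fov_x), round(k[2] * fov_y))
  if (all(kp == 0)) {
    stop_sdrsim("pattern period exceeds the field of view; cannot snap",
                "sdrsim_invalid_parameter")
  }
  k_new <- c(kp[1] / fov_x, kp[2] / fov_y)
  pattern$period_nm <- 1 / sqrt(sum(k_new^2))
  pattern$orientation_deg <- atan2(k_new[2], k_new[1]) * 180 / pi
  pattern
}

#' Default three-orientation illumination patterns
#'
#' Orientations 0, 60 and 120 degrees, period 220 nm, modulation depth 0.9,
#' the canonical 0 / -120 / +120 degree phase steps, and mean intensity 500
#' photon-rate units. When a grid is supplied the wavevectors are snapped to
#' integer spectral pixels (see [snap_pattern_to_grid()]) so the spatial- and
#' frequency-domain reconstructions see identical physics.
#'
#' @param grid Optional [grid2d()] used for spectral-pixel snapping.
#' @param period_nm Fringe period, default 220 nm.
#' @param orientations_deg Pattern orientations, default `c(0, 60, 120)`.
#' @param modulation_depth Fringe contrast, default 0.9.
#' @param mean_intensity Mean intensity `I0`, default 500.
#' @param initial_phase_rad Initial fringe phase, default 0.
#' @return List of three [sinusoid_pattern()] objects.
#' @export
default_patterns <- function(grid = NULL, period_nm = 220,
                             orientations_deg = c(0, 60, 120),
                             modulation_depth = 0.9, mean_intensity = 500,
                             initial_phase_rad = 0) {
  pats <- lapply(orientations_deg, function(th) {
    sinusoid_pattern(period_nm, orientation_deg = th,
                     modulation_depth = modulation_depth,
                     mean_intensity = mean_intensity,
                     initial_phase_rad = initial_phase_rad)
  })
  if (!is.null(grid)) pats <- lapply(pats, snap_pattern_to_grid, grid = grid)
  pats
}

new_sim_stack <- function(frames, patterns, psf, grid, noise = NULL) {
  stopifnot(length(frames) == 9L, length(patterns) == 3L)
  structure(list(frames = frames, patterns = patterns, psf = psf,
                 grid = grid, noise = noise),
            class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  cat(sprintf("<sim_stack> 9 frames (%d x %d), T ~ %.4g nm, m = %.3g, %s\n",
              x$grid$n_rows, x$grid$n_cols, x$patterns[[1]]$period_nm,
              x$patterns[[1]]$modulation_depth,
              if (is.null(x$noise)) "noise-free" else
                sprintf("noisy (seed %d)", x$noise$seed)))
  invisible(x)
}

# 1-based frame index for orientation d, phase j (orientation-major order).
frame_index <- function(d, j) (d - 1L) * 3L + j

#' Simulate a nine-frame raw SIM stack
#'
#' Each raw frame is the convolution of the object density times one
#' phase-shifted illumination pattern with the detection PSF (computed by FFT
#' with periodic boundaries), optionally followed by Poisson sampling and
#' additive Gaussian read noise; noisy frames are clipped at zero. Frames are
#' ordered orientation-major, phase-minor.
#'
#' @param object A `scene_object`.
#' @param patterns List of exactly three [sinusoid_pattern()]s (one per
#'   orientation), each with three phase shifts. A warning is issued if they
#'   do not share mean intensity and modulation depth.
#' @param psf A [gaussian_psf()].
#' @param noise A [noise_model()] or `NULL` for noise-free frames.
#' @return A `sim_stack`.
#' @examples
#' g <- grid2d(64, 64, 32.5)
#' obj <- make_point_source(g)
#' stk <- simulate_sim_stack(obj, default_patterns(g), gaussian_psf(200))
#' @export
simulate_sim_stack <- function(object, patterns, psf, noise = NULL) {
  stopifnot(inherits(object, "scene_object"), inherits(psf, "gaussian_psf"))
  if (inherits(patterns, "sinusoid_pattern")) patterns <- list(patterns)
  if (length(patterns) != 3L ||
      !all(vapply(patterns, inherits, logical(1), "sinusoid_pattern"))) {
    stop_sdrsim("exactly three sinusoid_pattern orientations are required",
                "sdrsim_shape_error")
  }
  if (any(vapply(patterns, function(p) length(p$phase_shifts_rad), integer(1)) != 3L)) {
    stop_sdrsim("each pattern must carry three phase shifts", "sdrsim_shape_error")
  }
  i0 <- vapply(patterns, `[[`, numeric(1), "mean_intensity")
  mm <- vapply(patterns, `[[`, numeric(1), "modulation_depth")
  if (diff(range(i0)) > 1e-12 * max(i0) || diff(range(mm)) > 1e-12) {
    warning("patterns do not share mean intensity / modulation depth")
  }
  grid <- object$grid
  otf <- fft2(ifftshift2(gaussian_psf_image(psf, grid)))
  frames <- vector("list", 9L)
  for (d in 1:3) {
    for (j in 1:3) {
      emission <- object$image * illumination_image(patterns[[d]], j, grid)
      frames[[frame_index(d, j)]] <- Re(ifft2(fft2(emission) * otf))
    }
  }
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    frames <- with_local_seed(noise$seed, {
      lapply(frames, function(f) {
        v <- if (noise$poisson) {
          matrix(stats::rpois(length(f), pmax(f, 0)), nrow(f), ncol(f))
        } else f
        if (noise$read_noise_sd > 0) {
          v <- v + matrix(stats::rnorm(length(f), sd = noise$read_noise_sd),
                          nrow(f), ncol(f))
        }
        pmax(v, 0)
      })
    })
  }
  new_sim_stack(frames, patterns, psf, grid, noise)
}

#' Widefield baseline image of a stack
#'
#' Phase-averaging the sinusoidally illuminated frames cancels the modulation,
#' leaving the uniform-illumination (diffraction-limited) image `I0 (O * H)`.
#' The average over all nine frames is used.
#'
#' @param stack A `sim_stack`.
#' @return Numeric matrix.
#' @export
widefield_image <- function(stack) {
  stopifnot(inherits(stack, "sim_stack"))
  Reduce(`+`, stack$frames) / length(stack$frames)
}
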