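# Shared fixtures: small grids and stacks kept cheap so each file stays fast.

tiny_grid <- function(n = 64, px = 32.5) grid2d(n, n, px)

std_psf <- function() gaussian_psf(200)

# One snapped pattern along x on the given grid.
pattern_x <- function(grid, period_nm = 220, m = 0.9, i0 = 1, phi0 = 0) {
  snap_pattern_to_grid(
    sinusoid_pattern(period_nm, orientation_deg = 0, modulation_depth = m,
                     mean_intensity = i0, initial_phase_rad = phi0),
    grid)
}

# Noise-free point-source stack on a small grid (cached per session).
point_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- tiny_grid(128)
      cache <<- simulate_sim_stack(make_point_source(g), default_patterns(g),
                                   std_psf())
    }
    cache
  }
})

# Evaluate the illumination at arbitrary physical points (independent of the
# raster) - used by brute-force identity oracles.
illum_at <- function(pattern, shift_index, x_nm, y_nm) {
  k <- pattern_wavevector(pattern)
  pattern$mean_intensity *
    (1 + pattern$modulation_depth *
       cos(2 * pi * (k[1] * x_nm + k[2] * y_nm) +
             pattern$initial_phase_rad -
             pattern$phase_shifts_rad[shift_index]))
}

truth_centers <- function(scene) {
  data.frame(x_nm = scene$truth$x_nm, y_nm = scene$truth$y_nm)
}
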