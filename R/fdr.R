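# Frequency-domain reconstruction (FDR): the classical SIM pipeline used as
# the in-package reference. Frame spectra are unmixed into the 0 and +/-1
# object bands, the sidebands are translated to their true frequencies on a
# 2x zero-padded spectral grid, all bands are recombined with generalized
# Wiener weighting, and one inverse FFT yields the SR image.

#' Phase mixing matrix of a three-step acquisition
#'
#' Row `j` gives the weights with which raw frame `j`'s spectrum mixes the
#' object's zero and +/- first-order bands:
#' `I0 * [1, (m/2) e^{i(phi0 - psi_j)}, (m/2) e^{-i(phi0 - psi_j)}]`.
#' The matrix is full-rank exactly when the three fringe phases are distinct
#' (modulo 2 pi) and `m > 0` - the algebraic reason at least three phase
#' steps are needed to solve for the three bands (or, equivalently, the three
#' SDR coefficient fields).
#'
#' @param phase_shifts_rad Fringe phase shifts `psi_j` (any length >= 1).
#' @param modulation_depth Fringe contrast `m`.
#' @param mean_intensity Mean intensity `I0`.
#' @param initial_phase_rad Initial fringe phase `phi0`.
#' @return Complex matrix with one row per phase step and three columns.
#' @export
phase_mixing_matrix <- function(phase_shifts_rad, modulation_depth,
                                mean_intensity = 1, initial_phase_rad = 0) {
  m <- modulation_depth
  ph <- initial_phase_rad - phase_shifts_rad
  mean_intensity * cbind(
    rep(1 + 0i, length(ph)),
    (m / 2) * exp(1i * ph),
    (m / 2) * exp(-1i * ph)
  )
}

matrix_rank <- function(M, tol = 1e-10) {
  s <- svd(M)$d
  sum(s > tol * max(s))
}

#' Separate one orientation's spectra into object bands
#'
#' Fourier-transforms the orientation's three raw frames and solves, per
#' frequency pixel, the 3x3 linear system given by [phase_mixing_matrix()],
#' yielding the OTF-attenuated object bands: `band0 = O(f) H(f)`,
#' `band_plus = O(f - k0) H(f)`, `band_minus = O(f + k0) H(f)`.
#'
#' @param stack A `sim_stack`.
#' @param orientation_index Orientation 1, 2 or 3.
#' @return A `spectrum_bands` object: complex matrices `band0`, `band_plus`,
#'   `band_minus` in wrap-around DFT order, the orientation's `pattern`, and
#'   `carrier_pix`, the wavevector in frequency pixels `(kx_pix, ky_pix)`.
#' @export
separate_bands <- function(stack, orientation_index) {
  stopifnot(inherits(stack, "sim_stack"))
  d <- as.integer(orientation_index)
  if (is.na(d) || d < 1L || d > 3L) {
    stop_sdrsim("orientation_index must be 1, 2 or 3", "sdrsim_index_error")
  }
  pattern <- stack$patterns[[d]]
  M <- phase_mixing_matrix(pattern$phase_shifts_rad, pattern$modulation_depth,
                           pattern$mean_intensity, pattern$initial_phase_rad)
  if (nrow(M) != 3L || matrix_rank(M) < 3L) {
    stop_sdrsim(
      "singular phase mixing matrix: need three distinct phases and m > 0",
      "sdrsim_singular_matrix")
  }
  Minv <- solve(M)
  spectra <- lapply(1:3, function(j) fft2(stack$frames[[frame_index(d, j)]]))
  bands <- lapply(1:3, function(k) {
    Minv[k, 1] * spectra[[1]] + Minv[k, 2] * spectra[[2]] +
      Minv[k, 3] * spectra[[3]]
  })
  k <- pattern_wavevector(pattern)
  carrier_pix <- c(k[1] * stack$grid$n_cols * stack$grid$pixel_size_nm,
                   k[2] * stack$grid$n_rows * stack$grid$pixel_size_nm)
  structure(
    list(band0 = bands[[1]], band_plus = bands[[2]], band_minus = bands[[3]],
         pattern = pattern, carrier_pix = carrier_pix, grid = stack$grid),
    class = "spectrum_bands"
  )
}

# Translate a spectrum's frequency argument by `s` pixels: out(f) = A(f + s).
# Exact (circular) for integer s in wrap-around DFT order.
freq_shift <- function(A, s) circ_shift(A, round(s[2]), round(s[1]))

#' Shift and recombine separated bands into the SR image
#'
#' Embeds each band in a 2x zero-padded spectral grid (same frequency-pixel
#' spacing, doubled support, hence a 2x finer output raster over the same
#' field of view), translates the +/-1 bands by -/+ the carrier to their true
#' frequencies, and combines all bands across orientations by generalized
#' Wiener weighting: `sum_b band_b conj(OTF_b) / (sum_b |OTF_b|^2 + w^2)` with
#' each band's OTF translated alongside it. One inverse FFT and a nonnegative
#' clip give the SR image.
#'
#' Carriers must land on integer frequency pixels (see
#' [snap_pattern_to_grid()]); subpixel carriers are rounded with a warning.
#'
#' @param bands_list List of `spectrum_bands` (one per orientation).
#' @param otf_padded Complex OTF sampled on the padded spectral grid, as from
#'   [otf_from_psf()] of the PSF rendered on the padded grid.
#' @param wiener_w Wiener regularization constant (> 0).
#' @param pad_factor Spectral padding factor (default 2).
#' @return Numeric matrix of dimension `pad_factor * dim(input frames)`.
#' @export
shift_and_recombine <- function(bands_list, otf_padded, wiener_w = 0.05,
                                pad_factor = 2L) {
  check_number(wiener_w, "wiener_w", positive = TRUE)
  if (inherits(bands_list, "spectrum_bands")) bands_list <- list(bands_list)
  stopifnot(all(vapply(bands_list, inherits, logical(1), "spectrum_bands")))
  pad_factor <- as.integer(pad_factor)
  dims <- dim(bands_list[[1]]$band0)
  NR <- pad_factor * dims[1]; NC <- pad_factor * dims[2]
  if (!all(dim(otf_padded) == c(NR, NC))) {
    stop_sdrsim("otf_padded does not match the padded spectral grid",
                "sdrsim_shape_error")
  }
  num <- matrix(0 + 0i, NR, NC)
  den <- matrix(0, NR, NC)
  for (b in bands_list) {
    if (!all(dim(b$band0) == dims)) {
      stop_sdrsim("bands do not share one spectral grid", "sdrsim_shape_error")
    }
    s <- b$carrier_pix
    if (max(abs(s - round(s))) > 1e-6) {
      warning(sprintf(
        "subpixel carrier (%.4g, %.4g) rounded to the nearest frequency pixel",
        s[1], s[2]))
    }
    s <- round(s)
    if (any(abs(s) > c(NC, NR) %/% 2L)) {
      stop_sdrsim("carrier frequency outside the padded spectral support",
                  "sdrsim_frequency_range_error")
    }
    pieces <- list(
      list(spec = pad_spectrum(b$band0, pad_factor), shift = c(0, 0)),
      list(spec = pad_spectrum(b$band_plus, pad_factor), shift = s),
      list(spec = pad_spectrum(b$band_minus, pad_factor), shift = -s)
    )
    for (p in pieces) {
      otf_s <- freq_shift(otf_padded, p$shift)
      num <- num + freq_shift(p$spec, p$shift) * Conj(otf_s)
      den <- den + Mod(otf_s)^2
    }
  }
  # Normalize the combined transfer function to unit DC gain before adding
  # w^2, so the Wiener constant means the same thing here as in
  # wiener_deconvolve() (which normalizes its OTF to 1 at zero frequency).
  s0 <- den[1, 1]
  combined <- (num / s0) / (den / s0 + wiener_w^2)
  out <- ifft2(combined)
  res <- max(abs(Im(out))) / max(abs(Re(out)), .Machine$double.eps)
  if (res > 1e-6) {
    warning(sprintf("imaginary residue %.3g after recombination", res))
  }
  pmax(Re(out), 0)
}

#' Frequency-domain SIM reconstruction
#'
#' The classical five-step pipeline over all three orientations: FFT of the
#' nine raw frames, band separation per orientation, spectral translation of
#' the sidebands, generalized Wiener recombination into one enlarged
#' spectrum, and an inverse FFT. The output raster is `pad_factor` times
#' finer than the input over the same field of view.
#'
#' @inheritParams sdr_reconstruct
#' @param pad_factor Spectral padding factor (default 2).
#' @return A `recon_result` with `method = "fdr"`; `$grid` describes the finer
#'   output raster.
#' @export
fdr_reconstruct <- function(stack, wiener_w = 0.05, pad_factor = 2L) {
  stopifnot(inherits(stack, "sim_stack"))
  if (length(stack$frames) != 9L) {
    stop_sdrsim("a 9-frame stack (3 orientations x 3 phases) is required",
                "sdrsim_shape_error")
  }
  pad_factor <- as.integer(pad_factor)
  grid_out <- grid2d(pad_factor * stack$grid$n_rows,
                     pad_factor * stack$grid$n_cols,
                     stack$grid$pixel_size_nm / pad_factor)
  # The padded-grid OTF: same pixel pitch as the acquisition, doubled extent.
  otf_padded <- otf_from_psf(gaussian_psf_image(stack$psf, grid_out))
  bands <- lapply(1:3, function(d) separate_bands(stack, d))
  img <- shift_and_recombine(bands, otf_padded, wiener_w, pad_factor)
  epsf <- effective_psf(stack$psf, stack$patterns, stack$grid)
  new_recon_result(
    sr_image = img,
    effective_psf = epsf,
    method = "fdr",
    params = list(wiener_w = wiener_w, pad_factor = pad_factor,
                  patterns = stack$patterns, psf = stack$psf,
                  noise = stack$noise,
                  package_version = as.character(utils::packageVersion("sdrsim"))),
    unclipped = NULL,
    grid = grid_out
  )
}
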