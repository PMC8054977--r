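test_that("phase mixing matrix rank reflects the number of distinct phases", {
  # two distinct phases cannot separate three bands
  M2 <- phase_mixing_matrix(c(0, 2 * pi / 3), 0.9)
  expect_equal(sdrsim:::matrix_rank(M2), 2)
  M2b <- phase_mixing_matrix(c(0, 2 * pi / 3, 2 * pi / 3), 0.9)
  expect_equal(sdrsim:::matrix_rank(M2b), 2)
  M3 <- phase_mixing_matrix(c(0, -2 * pi / 3, 2 * pi / 3), 0.9)
  expect_equal(sdrsim:::matrix_rank(M3), 3)
  expect_equal(sdrsim:::matrix_rank(phase_mixing_matrix(c(0, 1, 2), 0)), 1)
})

test_that("band separation recovers the OTF for a point source and rejects singular setups", {
  stk <- point_stack()
  b <- separate_bands(stk, 1)
  otf <- otf_from_psf(gaussian_psf_image(stk$psf, stk$grid))
  # delta object at the origin pixel: |band0| = const * |OTF| (the off-center
  # delta contributes only a pure phase ramp)
  mb <- Mod(b$band0)
  expect_lt(max(abs(mb / mb[1, 1] - Mod(otf))), 1e-6)
  # +/- bands are conjugate-reflected partners for real input
  bp <- b$band_plus
  bm_reflect <- Conj(bp[c(1, nrow(bp):2), c(1, ncol(bp):2)])
  expect_lt(max(Mod(b$band_minus - bm_reflect)), 1e-9 * max(Mod(bp)))

  stk_bad <- stk
  stk_bad$patterns[[1]]$modulation_depth <- 0
  expect_error(separate_bands(stk_bad, 1), class = "sdrsim_singular_matrix")
  stk_dup <- stk
  stk_dup$patterns[[2]]$phase_shifts_rad <- c(0, 0, 2 * pi / 3)
  expect_error(separate_bands(stk_dup, 2), class = "sdrsim_singular_matrix")
})

test_that("zero carriers reduce recombination to widefield Wiener deconvolution", {
  g <- tiny_grid(96)
  psf <- std_psf()
  # effectively uniform illumination: carrier ~ 0, distinct phases keep the
  # mixing matrix invertible, so all three bands coincide with the zero band
  pats0 <- lapply(c(0, 60, 120), function(th) {
    sinusoid_pattern(1e9, orientation_deg = th, modulation_depth = 0.9,
                     mean_intensity = 500)
  })
  obj <- make_bead_field(g, 3, min_separation_nm = 500, seed = 6,
                         margin_nm = 650)
  stk <- simulate_sim_stack(obj, pats0, psf)
  bands <- lapply(1:3, function(d) separate_bands(stk, d))
  gp <- grid2d(192, 192, g$pixel_size_nm / 2)
  otf_p <- otf_from_psf(gaussian_psf_image(psf, gp))
  out <- suppressWarnings(shift_and_recombine(bands, otf_p, wiener_w = 0.05))
  direct <- wiener_deconvolve(fourier_upsample(widefield_image(stk), 2),
                              gaussian_psf_image(psf, gp), 0.05)
  direct <- pmax(direct, 0)
  scale <- sum(out * direct) / sum(direct^2)
  expect_lt(nrmse(out, scale * direct, crop = 30), 1e-6)
})

test_that("recombined spectrum extends beyond the widefield support", {
  stk <- point_stack()
  res <- fdr_reconstruct(stk, 1e-4)
  spec <- Mod(fft(res$sr_image))
  n <- nrow(spec)
  fx <- sdrsim:::fft_freq(n, res$grid$pixel_size_nm)
  fr <- sqrt(outer(fx^2, fx^2, `+`))
  # widefield OTF is ~1e-7 at 11/1000 cycles/nm; SIM content must exceed it
  ring <- fr > 0.011 & fr < 0.013
  expect_gt(max(spec[ring]) / max(spec), 1e-4)
  wf_spec <- Mod(fft(fourier_upsample(widefield_image(stk), 2)))
  expect_gt(max(spec[ring]) / max(spec),
            100 * max(wf_spec[ring]) / max(wf_spec))
})

test_that("integer-pixel carrier shifts are exactly reversible", {
  set.seed(8)
  A <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  s <- c(7, -12)
  back <- sdrsim:::freq_shift(sdrsim:::freq_shift(A, s), -s)
  expect_equal(back, A)
})

test_that("FDR is linear, zero on zero stacks, and resolves the 130 nm pair", {
  g <- grid2d(256, 256, 32.5)
  pats <- default_patterns(g)
  tp <- make_two_point(g, 130, 0)
  stk <- simulate_sim_stack(tp, pats, std_psf())
  res <- fdr_reconstruct(stk, 0.05)
  expect_gte(two_point_dip(res$sr_image, res$grid, truth_centers(tp)), 0.2)
  stk2 <- stk; stk2$frames <- lapply(stk$frames, function(f) 2 * f)
  res2 <- fdr_reconstruct(stk2, 0.05)
  expect_equal(res2$sr_image, 2 * res$sr_image, tolerance = 1e-9)
  stk0 <- stk; stk0$frames <- lapply(stk$frames, function(f) f * 0)
  expect_equal(fdr_reconstruct(stk0, 0.05)$sr_image,
               matrix(0, 512, 512))
})

test_that("SDR and FDR produce near-identical noiseless bead reconstructions", {
  g <- grid2d(256, 256, 32.5)
  pats <- default_patterns(g)
  obj <- make_bead_field(g, 10, min_separation_nm = 700, seed = 3,
                         margin_nm = 700)
  stk <- simulate_sim_stack(obj, pats, std_psf())
  w <- 1e-6  # light regularization: no noise to suppress
  sdr <- sdr_reconstruct(stk, w)
  fdr <- fdr_reconstruct(stk, w)
  up <- pmax(fourier_upsample(sdr$sr_image, 2), 0)
  expect_gte(image_similarity(up, fdr$sr_image, crop_margin = 40), 0.99)
})
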