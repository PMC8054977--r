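test_that("bead fields honor count, separation, determinism and packing limits", {
  g <- grid2d(256, 256, 32.5)
  sc <- make_bead_field(g, 20, min_separation_nm = 500, seed = 7)
  expect_length(sc$truth$x_nm, 20)
  dd <- as.matrix(dist(cbind(sc$truth$x_nm, sc$truth$y_nm)))
  expect_true(all(dd[upper.tri(dd)] >= 500))
  co <- grid_coords(g)
  expect_true(all(sc$truth$x_nm >= min(co$x) & sc$truth$x_nm <= max(co$x)))
  expect_identical(sc$image, make_bead_field(g, 20, 500, seed = 7)$image)
  expect_false(identical(sc$image, make_bead_field(g, 20, 500, seed = 8)$image))
  expect_error(
    make_bead_field(g, 500, min_separation_nm = 600, seed = 1,
                    max_attempts = 2000L),
    class = "sdrsim_packing_error")
})

test_that("two-point targets encode the separation and axis symmetry", {
  g <- grid2d(128, 128, 32.5)
  sc <- make_two_point(g, 130, 0)
  d <- sqrt(diff(sc$truth$x_nm)^2 + diff(sc$truth$y_nm)^2)
  expect_equal(d, 130)
  sc90 <- make_two_point(g, 130, 90)
  expect_identical(t(sc$image), sc90$image)
  expect_error(make_two_point(g, 10, 0), class = "sdrsim_invalid_parameter")
  expect_error(make_two_point(g, 128 * 32.5, 0),
               class = "sdrsim_invalid_parameter")
})

test_that("bar targets are binary with ~50% duty cycle", {
  g <- grid2d(128, 128, 32.5)
  sc <- make_bar_target(g, 325, n_bars = 3)  # 10-pixel period
  expect_setequal(unique(as.vector(sc$image)), c(0, sc$truth$amplitude))
  covered <- 3 * 325 / 32.5 * (3 * 325 / 32.5)  # bar extent in pixels^2
  expect_equal(sum(sc$image > 0) / covered, 0.5, tolerance = 0.05)
  expect_error(make_bar_target(g, 40, 3), class = "sdrsim_invalid_parameter")
})

test_that("noise-free frames are linear in the object and phase-average to widefield", {
  g <- tiny_grid(96)
  psf <- std_psf()
  pats <- default_patterns(g)
  obj <- make_bead_field(g, 3, min_separation_nm = 500, seed = 2,
                         margin_nm = 650)
  stk <- simulate_sim_stack(obj, pats, psf)
  # zero object -> zero frames
  zero <- make_uniform_field(g, 0)
  stk0 <- simulate_sim_stack(zero, pats, psf)
  expect_true(all(vapply(stk0$frames, function(f) max(abs(f)), numeric(1)) == 0))
  # linearity
  obj3 <- obj; obj3$image <- 3 * obj$image
  stk3 <- simulate_sim_stack(obj3, pats, psf)
  for (k in c(1, 5, 9)) {
    expect_equal(stk3$frames[[k]], 3 * stk$frames[[k]], tolerance = 1e-10)
  }
  # per-orientation phase sum = 3 I0 (O * H): the widefield baseline
  h <- gaussian_psf_image(psf, g)
  conv <- Re(fft(fft(obj$image) * fft(sdrsim:::ifftshift2(h)),
                 inverse = TRUE)) / length(obj$image)
  i0 <- pats[[1]]$mean_intensity
  for (d in 1:3) {
    s <- stk$frames[[3 * d - 2]] + stk$frames[[3 * d - 1]] + stk$frames[[3 * d]]
    expect_equal(s, 3 * i0 * conv, tolerance = 1e-6)
  }
  expect_equal(widefield_image(stk), i0 * conv, tolerance = 1e-6)
})

test_that("uniform-scene frame modulation contrast equals m * |OTF(k0)|", {
  g <- grid2d(128, 128, 32.5)
  psf <- std_psf()
  pat <- pattern_x(g)
  pats <- list(pat, pat, pat)
  stk <- simulate_sim_stack(make_uniform_field(g, 10), pats, psf)
  f <- stk$frames[[1]]
  # regress interior pixels on the known fringe phase
  co <- grid_coords(g)
  k <- pattern_wavevector(pat)
  keep <- 21:108
  ph <- outer(2 * pi * k[2] * co$y[keep], 2 * pi * k[1] * co$x[keep], `+`) +
    pat$initial_phase_rad - pat$phase_shifts_rad[1]
  fit <- lm(as.vector(f[keep, keep]) ~ cos(as.vector(ph)) + sin(as.vector(ph)))
  contrast <- sqrt(sum(coef(fit)[2:3]^2)) / coef(fit)[1]
  # independent oracle: direct discrete-space FT of the PSF kernel at k0
  h <- gaussian_psf_image(psf, g)
  expected <- pat$modulation_depth *
    abs(sum(h * cos(outer(2 * pi * k[2] * co$y, 2 * pi * k[1] * co$x, `+`))) / sum(h))
  expect_equal(unname(contrast), expected, tolerance = 1e-3)
})

test_that("seeded noise is bit-reproducible and preserves the mean count", {
  g <- tiny_grid(64)
  pats <- default_patterns(g)
  obj <- make_uniform_field(g, 10)
  nm <- noise_model(poisson = TRUE, read_noise_sd = 2, seed = 99)
  a <- simulate_sim_stack(obj, pats, std_psf(), nm)
  b <- simulate_sim_stack(obj, pats, std_psf(), nm)
  expect_identical(a$frames, b$frames)
  c <- simulate_sim_stack(obj, pats, std_psf(), noise_model(seed = 100))
  expect_false(identical(a$frames, c$frames))
  clean <- simulate_sim_stack(obj, pats, std_psf())
  for (k in c(1, 9)) {
    lam <- clean$frames[[k]]
    se <- sqrt(sum(lam + 4)) / length(lam)  # Poisson var + read var, mean over pixels
    expect_lt(abs(mean(a$frames[[k]]) - mean(lam)), 3 * se)
  }
})

test_that("noise does not disturb the caller's RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_sim_stack(make_uniform_field(tiny_grid(64), 5),
                               default_patterns(tiny_grid(64)), std_psf(),
                               noise_model(seed = 42)))
  expect_identical(.Random.seed, before)
})
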