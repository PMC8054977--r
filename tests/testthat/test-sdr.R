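test_that("coefficient fields match the analytic raised cosine and sum to 1/I0", {
  g <- tiny_grid(64)
  # m = 1, I0 = 1, phi0 = 0: at the origin 2 pi k.r + phi0 = 0, so c1 = (1+2)/3
  p <- sinusoid_pattern(220, modulation_depth = 1, mean_intensity = 1)
  cs <- sdr_coefficients(p, g)
  i0 <- 64 %/% 2 + 1
  expect_equal(cs$fields[[1]][i0, i0], 1.0)
  # bounds (1 +/- 2/m) / (3 I0)
  m <- 0.7; I0 <- 4
  p2 <- sinusoid_pattern(307, orientation_deg = 35, modulation_depth = m,
                         mean_intensity = I0, initial_phase_rad = 0.4)
  cs2 <- sdr_coefficients(p2, g)
  for (f in cs2$fields) {
    expect_true(all(f >= (1 - 2 / m) / (3 * I0) - 1e-12))
    expect_true(all(f <= (1 + 2 / m) / (3 * I0) + 1e-12))
  }
  s <- cs2$fields[[1]] + cs2$fields[[2]] + cs2$fields[[3]]
  expect_equal(s, matrix(1 / I0, 64, 64), tolerance = 1e-9)
  expect_error(
    sdr_coefficients(sinusoid_pattern(220, phase_shifts_rad = c(0, 1, 2, 3)), g),
    class = "sdrsim_unsupported_configuration")
})

test_that("superposition identity sum_j c_j(x) I(x'-d_j) = 1 + cos(2 pi k0 (x-x')) holds", {
  g <- tiny_grid(48)
  co <- grid_coords(g)
  set.seed(4)
  worst <- 0
  for (draw in 1:10) {
    p <- sinusoid_pattern(runif(1, 150, 600),
                          orientation_deg = runif(1, 0, 180),
                          modulation_depth = runif(1, 0.05, 1),
                          mean_intensity = runif(1, 0.2, 5),
                          initial_phase_rad = runif(1, 0, 2 * pi))
    cs <- sdr_coefficients(p, g)
    n <- 1000
    ii <- sample(48, n, TRUE); jj <- sample(48, n, TRUE)
    xp <- runif(n, -700, 700); yp <- runif(n, -700, 700)
    lhs <- 0
    for (j in 1:3) {
      lhs <- lhs + cs$fields[[j]][cbind(ii, jj)] * illum_at(p, j, xp, yp)
    }
    k <- pattern_wavevector(p)
    rhs <- 1 + cos(2 * pi * (k[1] * (co$x[jj] - xp) + k[2] * (co$y[ii] - yp)))
    worst <- max(worst, max(abs(lhs - rhs)))
  }
  expect_lt(worst, 1e-9)
})

test_that("coefficient fields are cached per pattern and grid", {
  g <- tiny_grid(32)
  p <- sinusoid_pattern(250, orientation_deg = 10)
  a <- sdr_coefficients(p, g)
  b <- sdr_coefficients(p, g)
  expect_true(identical(a, b))
  d <- sdr_coefficients(p, g, use_cache = FALSE)
  expect_equal(a$fields, d$fields)
})

test_that("point-source superposition reproduces the effective PSF exactly", {
  stk <- point_stack()
  g <- stk$grid
  amp <- 25
  for (d in 1:3) {
    sup <- sdr_superpose(stk, d)
    P <- effective_psf(stk$psf, stk$patterns[[d]], g)$values * amp
    expect_lt(nrmse(sup, P, crop = 18), 1e-6)
  }
  nd <- sdr_reconstruct(stk, deconvolve = FALSE)
  expect_identical(nd$method, "sdr-nodeconv")
  Pc <- effective_psf(stk$psf, stk$patterns, g)$values * amp
  expect_lt(nrmse(nd$unclipped, Pc, crop = 18), 1e-6)
})

test_that("uniform scenes superpose to a constant and zero frames to zero", {
  g <- tiny_grid(96)
  pats <- default_patterns(g)
  stk <- simulate_sim_stack(make_uniform_field(g, 7), pats, std_psf())
  sup <- sdr_superpose(stk, 1)
  inner <- crop_border(sup, 18)
  expect_lt(max(abs(inner - mean(inner))) / mean(inner), 1e-6)
  stk0 <- simulate_sim_stack(make_uniform_field(g, 0), pats, std_psf())
  expect_equal(sdr_superpose(stk0, 2), matrix(0, 96, 96))
})

test_that("Wiener deconvolution inverts noise-free blur and is linear", {
  g <- tiny_grid(128)
  pats <- default_patterns(g)
  psf <- std_psf()
  # spots wide enough to be band-limited within the effective-PSF support,
  # so near-exact inversion is possible
  obj <- make_bead_field(g, 4, min_separation_nm = 500, seed = 5,
                         margin_nm = 700, bead_diameter_nm = 150)
  P <- effective_psf(psf, pats, g)$values
  blurred <- Re(fft(fft(obj$image) *
                      fft(sdrsim:::ifftshift2(P)), inverse = TRUE)) / (128^2)
  rec <- wiener_deconvolve(blurred, P, w = 1e-6) / sum(P)
  expect_lt(nrmse(rec, obj$image, crop = 20), 1e-3)
  expect_equal(wiener_deconvolve(matrix(0, 128, 128), P, 0.05),
               matrix(0, 128, 128))
  x <- matrix(rnorm(128^2), 128, 128)
  expect_equal(wiener_deconvolve(5 * x, P, 0.05),
               5 * wiener_deconvolve(x, P, 0.05), tolerance = 1e-12)
  expect_error(wiener_deconvolve(x, P, w = 0), class = "sdrsim_invalid_parameter")
})

test_that("sdr_reconstruct is linear in the stack and fully provenanced", {
  stk <- point_stack()
  res <- sdr_reconstruct(stk, 0.05)
  stk2 <- stk
  stk2$frames <- lapply(stk$frames, function(f) 2.5 * f)
  res2 <- sdr_reconstruct(stk2, 0.05)
  expect_equal(res2$unclipped, 2.5 * res$unclipped, tolerance = 1e-9)
  expect_true(all(res$sr_image >= 0))
  expect_identical(res$method, "sdr")
  expect_equal(res$params$wiener_w, 0.05)
  expect_length(res$params$patterns, 3)
})

test_that("superposition is a pure spatial operation: no FFT is invoked", {
  counter <- new.env(); counter$n <- 0L
  suppressMessages(trace(fft, where = asNamespace("stats"), print = FALSE,
                         tracer = function() counter$n <- counter$n + 1L))
  on.exit(suppressMessages(untrace(fft, where = asNamespace("stats"))),
          add = TRUE)
  stk <- point_stack()
  invisible(sdr_superpose(stk, 1))
  invisible(sdr_superpose(stk, 2) + sdr_superpose(stk, 3))
  expect_identical(counter$n, 0L)
  invisible(sdr_reconstruct(stk, 0.05))  # deconvolution is allowed to use FFTs
  expect_gt(counter$n, 0L)
})

test_that("the spatial path resolves a 130 nm pair that widefield cannot", {
  g <- grid2d(256, 256, 32.5)
  pats <- default_patterns(g)
  tp <- make_two_point(g, 130, 0)
  stk <- simulate_sim_stack(tp, pats, std_psf())
  ctr <- truth_centers(tp)
  dip_sdr <- two_point_dip(sdr_reconstruct(stk, 0.05)$sr_image, g, ctr)
  dip_wf <- two_point_dip(widefield_reconstruct(stk)$sr_image, g, ctr)
  expect_gte(dip_sdr, 0.2)
  expect_identical(dip_wf, 0)
})
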