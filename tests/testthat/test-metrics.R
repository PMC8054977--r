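test_that("Gaussian profile fits recover the FWHM and reject degenerate input", {
  x <- seq(0, 800, by = 10)
  sigma <- 200 / (2 * sqrt(2 * log(2)))  # 84.93 nm
  p <- 3 * exp(-(x - 400)^2 / (2 * sigma^2)) + 0.7
  fit <- fit_fwhm_profile(p, 10)
  expect_equal(fit$fwhm_nm, 200, tolerance = 0.5 / 200)
  expect_equal(fit$center_nm, 400, tolerance = 1e-6)
  expect_error(fit_fwhm_profile(rep(1, 50), 10), class = "sdrsim_fit_failure")
  expect_error(fit_fwhm_profile(p[1:5], 10), class = "sdrsim_invalid_parameter")
  # scale and offset invariance
  fit2 <- fit_fwhm_profile(25 * p + 13, 10)
  expect_equal(fit2$fwhm_nm, fit$fwhm_nm, tolerance = 1e-6)
})

test_that("the fitter stays within 5% of truth at peak-SNR 20", {
  x <- seq(0, 800, by = 10)
  sigma <- 200 / (2 * sqrt(2 * log(2)))
  clean <- exp(-(x - 400)^2 / (2 * sigma^2))
  ok <- 0L
  set.seed(2024)
  for (s in 1:100) {
    noisy <- clean + rnorm(length(x), sd = 1 / 20)
    f <- tryCatch(fit_fwhm_profile(noisy, 10), error = function(e) NULL)
    if (!is.null(f) && abs(f$fwhm_nm - 200) / 200 < 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("bead reports measure the widefield PSF and handle edge cases", {
  g <- grid2d(256, 256, 32.5)
  pats <- default_patterns(g)
  obj <- make_bead_field(g, 8, min_separation_nm = 700, seed = 9,
                         margin_nm = 700)
  stk <- simulate_sim_stack(obj, pats, std_psf())
  wf <- widefield_image(stk)
  rep <- bead_fwhm_report(wf, g, truth_centers(obj))
  expect_equal(rep$n_beads, 8)
  # 40 nm Gaussian beads through a 200 nm PSF: quadrature width ~204 nm
  expect_equal(rep$mean_fwhm_nm, sqrt(200^2 + 40^2), tolerance = 5 / 204)
  expect_identical(rep, bead_fwhm_report(wf, g, truth_centers(obj)))
  empty <- bead_fwhm_report(wf, g, data.frame(x_nm = numeric(0), y_nm = numeric(0)))
  expect_equal(empty$n_beads, 0)
  # overlapping windows are excluded, not fitted
  two <- data.frame(x_nm = c(0, 200), y_nm = c(0, 0))
  rep2 <- bead_fwhm_report(wf, g, two)
  expect_equal(rep2$n_beads, 0)
  expect_equal(nrow(rep2$excluded), 2)
  expect_error(bead_fwhm_report(wf, g, data.frame(x_nm = 4100, y_nm = 0)),
               class = "sdrsim_invalid_parameter")
})

test_that("bead report on the analytic effective PSF matches the 1-D curve", {
  g <- grid2d(128, 128, 10)  # fine raster for the kernel itself
  psf <- std_psf()
  pat <- sinusoid_pattern(220, orientation_deg = 0)
  ep <- effective_psf(psf, pat, g)
  rep <- bead_fwhm_report(ep$values, g, data.frame(x_nm = 0, y_nm = 0),
                          window_nm = 500)
  # along-axis FWHM from the dedicated fine 1-D profile
  ref <- psf_fwhm_curve(psf, 220)$fwhm_nm
  # the report averages x (modulated, ~ref) and y (unmodulated, 200 nm) cuts
  expect_equal(rep$mean_fwhm_nm, (ref + 200) / 2, tolerance = 10 / 150)
})

test_that("two-point dip contrast separates resolved from unresolved pairs", {
  g <- grid2d(256, 256, 32.5)
  psf <- std_psf()
  # fully resolved: two spots 3 x FWHM apart imaged at widefield resolution
  far <- make_two_point(g, 650, 0)
  stk <- simulate_sim_stack(far, default_patterns(g), psf)
  wf <- widefield_image(stk)
  expect_gt(two_point_dip(wf, g, truth_centers(far)), 0.9)
  # unresolved: 130 nm pair in widefield
  near <- make_two_point(g, 130, 0)
  stk2 <- simulate_sim_stack(near, default_patterns(g), psf)
  expect_identical(two_point_dip(widefield_image(stk2), g, truth_centers(near)), 0)
  expect_error(
    two_point_dip(wf, g, data.frame(x_nm = c(0, 0), y_nm = c(0, 0))),
    class = "sdrsim_invalid_parameter")
})

test_that("image similarity behaves as a Pearson correlation", {
  set.seed(1)
  a <- matrix(runif(400), 20, 20)
  expect_equal(image_similarity(a, a), 1)
  expect_equal(image_similarity(a, -a), -1)
  expect_equal(image_similarity(a, 3 * a + 2), 1)
  expect_error(image_similarity(a, matrix(1, 20, 20)),
               class = "sdrsim_undefined_correlation")
  expect_error(image_similarity(a, matrix(runif(100), 10, 10)),
               class = "sdrsim_shape_error")
})

test_that("tidiers and plots expose report and reconstruction summaries", {
  stk <- point_stack()
  res <- sdr_reconstruct(stk, 0.05)
  gl <- glance(res)
  expect_identical(gl$method, "sdr")
  expect_equal(gl$wiener_w, 0.05)
  td <- tidy(res)
  expect_equal(nrow(td), 128^2)
  rep <- bead_fwhm_report(res$sr_image, stk$grid,
                          data.frame(x_nm = 0, y_nm = 0), window_nm = 500)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_beads, 1)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_s3_class(ggplot2::autoplot(psf_fwhm_curve(std_psf(), c(200, 400))),
                  "ggplot")
})
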