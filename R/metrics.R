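# Resolution metrology: line-profile extraction, Gaussian-fit FWHM of bead
# images, two-point resolvability (dip contrast), and image similarity.

#' Sample an image along a line by bilinear interpolation
#'
#' @param image Numeric matrix on `grid`.
#' @param grid A [grid2d()].
#' @param p0_nm,p1_nm Physical endpoints `c(x, y)` in nanometres.
#' @param spacing_nm Sample spacing; default a quarter pixel.
#' @return A tibble with `t_nm` (distance from `p0_nm`) and `value`.
#' @export
profile_line <- function(image, grid, p0_nm, p1_nm,
                         spacing_nm = grid$pixel_size_nm / 4) {
  stopifnot(inherits(grid, "grid2d"), is.matrix(image),
            all(dim(image) == c(grid$n_rows, grid$n_cols)))
  len <- sqrt(sum((p1_nm - p0_nm)^2))
  if (len <= 0) {
    stop_sdrsim("profile endpoints coincide", "sdrsim_invalid_parameter")
  }
  t_nm <- seq(0, len, by = spacing_nm)
  xs <- p0_nm[1] + t_nm / len * (p1_nm[1] - p0_nm[1])
  ys <- p0_nm[2] + t_nm / len * (p1_nm[2] - p0_nm[2])
  tibble::tibble(t_nm = t_nm,
                 value = bilinear_sample(image, grid, xs, ys))
}

bilinear_sample <- function(image, grid, x_nm, y_nm) {
  org <- grid_origin_index(grid)
  jf <- x_nm / grid$pixel_size_nm + org["j"]
  if_ <- y_nm / grid$pixel_size_nm + org["i"]
  if (any(jf < 1 | jf > grid$n_cols | if_ < 1 | if_ > grid$n_rows)) {
    stop_sdrsim("profile leaves the image", "sdrsim_invalid_parameter")
  }
  j1 <- pmin(floor(jf), grid$n_cols - 1L); j2 <- j1 + 1L
  i1 <- pmin(floor(if_), grid$n_rows - 1L); i2 <- i1 + 1L
  fx <- jf - j1; fy <- if_ - i1
  image[cbind(i1, j1)] * (1 - fx) * (1 - fy) +
    image[cbind(i1, j2)] * fx * (1 - fy) +
    image[cbind(i2, j1)] * (1 - fx) * fy +
    image[cbind(i2, j2)] * fx * fy
}

#' Gaussian-fit FWHM of a 1-D intensity profile
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - x0)^2 / (2 sigma^2))`
#' (Levenberg-Marquardt); returns `2 sqrt(2 ln 2) * sigma`. The offset term
#' absorbs reconstruction background, and the result is invariant to affine
#' intensity rescaling of the profile.
#'
#' @param values Intensity samples (at least 7) with a single dominant peak.
#' @param sample_spacing_nm Distance between consecutive samples.
#' @return List with `fwhm_nm`, `center_nm` (peak position relative to the
#'   first sample), and `residual` (root-mean-square fit residual relative to
#'   the fitted amplitude).
#' @examples
#' x <- seq(-400, 400, by = 10)
#' p <- exp(-x^2 / (2 * 84.93^2))
#' fit_fwhm_profile(p, 10)$fwhm_nm
#' @export
fit_fwhm_profile <- function(values, sample_spacing_nm) {
  check_number(sample_spacing_nm, "sample_spacing_nm", positive = TRUE)
  if (length(values) < 7L || !all(is.finite(values))) {
    stop_sdrsim("need at least 7 finite samples", "sdrsim_invalid_parameter")
  }
  x <- (seq_along(values) - 1) * sample_spacing_nm
  rng <- max(values) - min(values)
  if (rng <= 0 || rng < 1e-12 * max(abs(values))) {
    stop_sdrsim("profile is flat; no peak to fit", "sdrsim_fit_failure")
  }
  off0 <- min(values); amp0 <- rng
  x0_0 <- x[which.max(values)]
  above <- which(values > off0 + amp0 / 2)
  sig0 <- max((x[max(above)] - x[min(above)]) * FWHM_TO_SIGMA,
              sample_spacing_nm)
  df <- data.frame(x = x, y = as.numeric(values))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ off + amp * exp(-(x - x0)^2 / (2 * sig^2)),
      data = df,
      start = list(off = off0, amp = amp0, x0 = x0_0, sig = sig0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    stop_sdrsim(
      sprintf("Gaussian fit did not converge (data range %.3g)", rng),
      "sdrsim_fit_failure")
  }
  cf <- stats::coef(fit)
  resid_rms <- sqrt(mean(stats::residuals(fit)^2)) / abs(cf[["amp"]])
  if (!is.finite(cf[["sig"]]) || abs(cf[["amp"]]) < 1e-12 * rng) {
    stop_sdrsim(sprintf("degenerate Gaussian fit (residual %.3g)", resid_rms),
                "sdrsim_fit_failure")
  }
  list(fwhm_nm = abs(cf[["sig"]]) / FWHM_TO_SIGMA,
       center_nm = cf[["x0"]],
       residual = resid_rms)
}

#' Per-bead FWHM report for a reconstructed image
#'
#' For each ground-truth bead center, extracts intensity profiles along both
#' image axes through the center (bilinear sampling at a quarter-pixel
#' spacing, window of `window_nm`), Gaussian-fits each, and averages the two
#' FWHMs. Beads whose analysis windows overlap another bead's are excluded so
#' every fit sees a single peak.
#'
#' @param image Numeric matrix on `grid`.
#' @param grid A [grid2d()].
#' @param truth_centers Data frame (or tibble) with columns `x_nm`, `y_nm`.
#' @param window_nm Profile window length; default 600 nm (3 x a 200 nm
#'   widefield FWHM).
#' @return An `fwhm_report`: tibble `per_bead` (`x_nm`, `y_nm`, `fwhm_nm`,
#'   `fit_residual`), `mean_fwhm_nm`, `sd_fwhm_nm`, `n_beads`, and a tibble
#'   `excluded` with a reason per skipped bead.
#' @export
bead_fwhm_report <- function(image, grid, truth_centers, window_nm = 600) {
  stopifnot(inherits(grid, "grid2d"))
  check_number(window_nm, "window_nm", positive = TRUE)
  tc <- as.data.frame(truth_centers)
  if (nrow(tc) == 0L) {
    return(new_fwhm_report(
      tibble::tibble(x_nm = numeric(0), y_nm = numeric(0),
                     fwhm_nm = numeric(0), fit_residual = numeric(0)),
      tibble::tibble(x_nm = numeric(0), y_nm = numeric(0),
                     reason = character(0)),
      window_nm))
  }
  if (!all(c("x_nm", "y_nm") %in% names(tc))) {
    stop_sdrsim("truth_centers needs columns x_nm and y_nm",
                "sdrsim_invalid_parameter")
  }
  co <- grid_coords(grid)
  half <- window_nm / 2
  inside <- tc$x_nm - half >= min(co$x) & tc$x_nm + half <= max(co$x) &
    tc$y_nm - half >= min(co$y) & tc$y_nm + half <= max(co$y)
  if (!all(inside)) {
    stop_sdrsim(sprintf(
      "%d bead center(s) lack the full %g nm window margin inside the image",
      sum(!inside), window_nm), "sdrsim_invalid_parameter")
  }
  n <- nrow(tc)
  overlapped <- rep(FALSE, n)
  if (n > 1L) {
    dd <- as.matrix(stats::dist(tc[, c("x_nm", "y_nm")]))
    diag(dd) <- Inf
    overlapped <- apply(dd < window_nm, 1, any)
  }
  spacing <- grid$pixel_size_nm / 4
  rows <- list(); excl <- list()
  for (b in seq_len(n)) {
    if (overlapped[b]) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        x_nm = tc$x_nm[b], y_nm = tc$y_nm[b],
        reason = "analysis window overlaps another bead")
      next
    }
    fits <- lapply(list(c(1, 0), c(0, 1)), function(axis) {
      pr <- profile_line(image, grid,
                         c(tc$x_nm[b], tc$y_nm[b]) - half * axis,
                         c(tc$x_nm[b], tc$y_nm[b]) + half * axis,
                         spacing)
      tryCatch(fit_fwhm_profile(pr$value, spacing), sdrsim_fit_failure = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        x_nm = tc$x_nm[b], y_nm = tc$y_nm[b], reason = "Gaussian fit failed")
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      x_nm = tc$x_nm[b], y_nm = tc$y_nm[b],
      fwhm_nm = mean(vapply(fits[ok], `[[`, numeric(1), "fwhm_nm")),
      fit_residual = mean(vapply(fits[ok], `[[`, numeric(1), "residual")))
  }
  new_fwhm_report(
    if (length(rows)) do.call(rbind, rows) else
      tibble::tibble(x_nm = numeric(0), y_nm = numeric(0),
                     fwhm_nm = numeric(0), fit_residual = numeric(0)),
    if (length(excl)) do.call(rbind, excl) else
      tibble::tibble(x_nm = numeric(0), y_nm = numeric(0),
                     reason = character(0)),
    window_nm)
}

new_fwhm_report <- function(per_bead, excluded, window_nm) {
  structure(
    list(per_bead = per_bead,
         excluded = excluded,
         mean_fwhm_nm = if (nrow(per_bead)) mean(per_bead$fwhm_nm) else NA_real_,
         sd_fwhm_nm = if (nrow(per_bead) > 1L) stats::sd(per_bead$fwhm_nm) else NA_real_,
         n_beads = nrow(per_bead),
         window_nm = window_nm),
    class = "fwhm_report")
}

#' @export
print.fwhm_report <- function(x, ...) {
  cat(sprintf("<fwhm_report> %d bead(s): mean FWHM %.4g +/- %.3g nm (%d excluded)\n",
              x$n_beads, x$mean_fwhm_nm, x$sd_fwhm_nm, nrow(x$excluded)))
  invisible(x)
}

#' Two-point resolvability (dip contrast)
#'
#' Samples the intensity profile along the line through two known emitter
#' positions (extended by half the separation beyond each) and measures
#' `dip = (min(peak1, peak2) - valley) / min(peak1, peak2)`, where the peaks
#' are the profile maxima on either side of the midpoint and the valley is
#' the minimum strictly between them. Returns 0 when no valley lies between
#' two distinct peaks - the unresolved case.
#'
#' @param image Numeric matrix on `grid`.
#' @param grid A [grid2d()].
#' @param centers Two-row data frame/matrix of emitter positions
#'   (`x_nm`, `y_nm`).
#' @return Dip contrast in `[0, 1]`.
#' @export
two_point_dip <- function(image, grid, centers) {
  cc <- as.matrix(as.data.frame(centers)[, c("x_nm", "y_nm")])
  if (nrow(cc) != 2L) {
    stop_sdrsim("exactly two centers are required", "sdrsim_invalid_parameter")
  }
  sep <- sqrt(sum((cc[2, ] - cc[1, ])^2))
  if (sep <= 0) {
    stop_sdrsim("the two centers coincide", "sdrsim_invalid_parameter")
  }
  u <- (cc[2, ] - cc[1, ]) / sep
  p0 <- cc[1, ] - 0.5 * sep * u
  p1 <- cc[2, ] + 0.5 * sep * u
  pr <- profile_line(image, grid, p0, p1, grid$pixel_size_nm / 4)
  mid <- (min(pr$t_nm) + max(pr$t_nm)) / 2
  left <- pr$t_nm < mid
  i1 <- which.max(ifelse(left, pr$value, -Inf))
  i2 <- which.max(ifelse(!left, pr$value, -Inf))
  if (i2 - i1 < 2L) return(0)
  valley <- min(pr$value[(i1 + 1L):(i2 - 1L)])
  lower_peak <- min(pr$value[i1], pr$value[i2])
  if (lower_peak <= 0 || valley >= lower_peak) return(0)
  (lower_peak - valley) / lower_peak
}

#' Pearson similarity of two images
#'
#' Correlation of border-cropped, intensity-normalized images; the statistic
#' used to operationalize "the two reconstructions are identical".
#'
#' @param a,b Numeric matrices of identical dimension (after cropping).
#' @param crop_margin Pixels removed from every side before comparison.
#' @return Pearson correlation coefficient.
#' @export
image_similarity <- function(a, b, crop_margin = 0L) {
  a <- crop_border(a, crop_margin)
  b <- crop_border(b, crop_margin)
  if (!all(dim(a) == dim(b))) {
    stop_sdrsim("images differ in size after cropping", "sdrsim_shape_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_sdrsim("correlation undefined for a constant image",
                "sdrsim_undefined_correlation")
  }
  stats::cor(as.vector(a), as.vector(b))
}
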