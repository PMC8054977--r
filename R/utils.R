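# Internal helpers: error conditions, seeded RNG scopes, FFT plumbing.

stop_sdrsim <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "sdrsim_error", "error", "condition")))
}

check_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_sdrsim(sprintf("`%s` must be a single finite number", name),
                "sdrsim_invalid_parameter")
  }
  if (positive && x <= 0) {
    stop_sdrsim(sprintf("`%s` must be > 0 (got %g)", name, x),
                "sdrsim_invalid_parameter")
  }
  if (nonnegative && x < 0) {
    stop_sdrsim(sprintf("`%s` must be >= 0 (got %g)", name, x),
                "sdrsim_invalid_parameter")
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream (the global .Random.seed is saved and restored).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Normalized root-mean-square error between two images
#'
#' RMSE of `a - ref` divided by the root-mean-square of the reference, after
#' optionally cropping a border of `crop` pixels from every side.
#'
#' @param a,ref Numeric matrices of identical dimensions.
#' @param crop Border width in pixels to exclude from the comparison.
#' @return A single nonnegative number.
#' @export
nrmse <- function(a, ref, crop = 0L) {
  stopifnot(all(dim(a) == dim(ref)))
  a <- crop_border(a, crop)
  ref <- crop_border(ref, crop)
  sqrt(mean((a - ref)^2)) / sqrt(mean(ref^2))
}

#' Crop a uniform pixel border from an image
#'
#' @param image Numeric matrix.
#' @param margin Number of pixels removed from each side.
#' @return The central sub-matrix.
#' @export
crop_border <- function(image, margin) {
  margin <- as.integer(margin)
  if (margin <= 0L) return(image)
  nr <- nrow(image); nc <- ncol(image)
  if (2L * margin >= nr || 2L * margin >= nc) {
    stop_sdrsim("crop margin leaves no pixels", "sdrsim_invalid_parameter")
  }
  image[(margin + 1L):(nr - margin), (margin + 1L):(nc - margin), drop = FALSE]
}

# --- FFT plumbing -----------------------------------------------------------

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Cyclic shift: out[i, j] = m[i + dy, j + dx] (indices wrap).
circ_shift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L + dy) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + dx) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

# Move the image origin pixel (floor(n/2) zero-based) to index (1, 1):
# the inverse FFT shift for this package's center convention.
ifftshift2 <- function(m) circ_shift(m, nrow(m) %/% 2L, ncol(m) %/% 2L)
fftshift2 <- function(m) circ_shift(m, -(nrow(m) %/% 2L), -(ncol(m) %/% 2L))

# DFT bin frequencies in cycles per physical unit, standard wrap-around order.
fft_freq <- function(n, d = 1) {
  k <- 0:(n - 1L)
  k[k > (n - 1L) %/% 2L] <- k[k > (n - 1L) %/% 2L] - n
  k / (n * d)
}

# Periodic (circular) convolution with a kernel whose peak sits at the grid's
# origin pixel. Exact for content away from borders by at least the kernel
# support.
fft_convolve <- function(image, kernel_centered) {
  stopifnot(all(dim(image) == dim(kernel_centered)))
  Re(ifft2(fft2(image) * fft2(ifftshift2(kernel_centered))))
}

# Zero-pad a DFT spectrum to `factor`x the bin count per axis (same bin
# spacing, new bins carry zero), i.e. Fourier interpolation onto a grid of
# `factor`x finer pixels over the same field of view. Amplitudes are rescaled
# so pixel values are preserved under the larger inverse FFT.
pad_spectrum <- function(F, factor = 2L) {
  nr <- nrow(F); nc <- ncol(F)
  NR <- factor * nr; NC <- factor * nc
  G <- matrix(0 + 0i, NR, NC)
  r0 <- (NR - nr) %/% 2L
  c0 <- (NC - nc) %/% 2L
  G[r0 + seq_len(nr), c0 + seq_len(nc)] <- fftshift2(F)
  ifftshift2(G) * factor^2
}

#' Upsample an image by Fourier interpolation
#'
#' Zero-pads the image's discrete spectrum so the output samples the same
#' field of view on a grid `factor` times finer in each direction. Used to put
#' spatial-domain reconstructions on the padded grid of the frequency-domain
#' pipeline for like-for-like comparison.
#'
#' @param image Numeric matrix.
#' @param factor Integer upsampling factor (default 2).
#' @return A numeric matrix of dimension `factor * dim(image)`.
#' @export
fourier_upsample <- function(image, factor = 2L) {
  factor <- as.integer(factor)
  check_number(factor, "factor", positive = TRUE)
  Re(ifft2(pad_spectrum(fft2(image), factor)))
}
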