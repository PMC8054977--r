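# On-disk conventions: 32-bit float multi-page TIFF for images, JSON sidecars
# for metadata and provenance. Every artifact is reproducible from its own
# sidecar (parameters + seed).
#
# TIFF pages are stored in [0, 1]: pixel counts are divided by a power-of-two
# intensity_scale recorded in the sidecar (so rescaling on read is exact in
# binary floating point; the only loss is the float32 mantissa).

STACK_SCHEMA_VERSION <- "1.0"

intensity_scale_for <- function(images) {
  mx <- max(vapply(images, max, numeric(1)), 0)
  if (mx <= 0) 1 else 2^ceiling(log2(mx))
}

pattern_to_list <- function(p) {
  list(orientation_deg = p$orientation_deg,
       period_nm = p$period_nm,
       modulation_depth = p$modulation_depth,
       mean_intensity = p$mean_intensity,
       initial_phase_rad = p$initial_phase_rad,
       phase_shifts_rad = p$phase_shifts_rad)
}

pattern_from_list <- function(l) {
  sinusoid_pattern(period_nm = l$period_nm,
                   orientation_deg = l$orientation_deg,
                   modulation_depth = l$modulation_depth,
                   mean_intensity = l$mean_intensity,
                   initial_phase_rad = l$initial_phase_rad,
                   phase_shifts_rad = unlist(l$phase_shifts_rad))
}

check_overwrite <- function(path, force) {
  if (file.exists(path) && !force) {
    stop_sdrsim(sprintf("'%s' exists; use force = TRUE to overwrite", path),
                "sdrsim_io_error")
  }
}

#' Build the JSON-ready metadata record of a stack
#'
#' @param stack A `sim_stack`.
#' @return A named list matching the sidecar schema.
#' @export
stack_metadata <- function(stack) {
  stopifnot(inherits(stack, "sim_stack"))
  list(
    schema_version = STACK_SCHEMA_VERSION,
    software = paste0("sdrsim ", utils::packageVersion("sdrsim")),
    frame_order = "orientation-major,phase-minor",
    n_rows = stack$grid$n_rows,
    n_cols = stack$grid$n_cols,
    pixel_size_nm = stack$grid$pixel_size_nm,
    psf_fwhm_nm = stack$psf$fwhm_nm,
    patterns = lapply(stack$patterns, pattern_to_list),
    noise = if (is.null(stack$noise)) NULL else
      list(poisson = stack$noise$poisson,
           read_noise_sd = stack$noise$read_noise_sd,
           seed = stack$noise$seed)
  )
}

#' Write a raw stack as 9-page TIFF plus JSON sidecar
#'
#' Pages are 32-bit float in orientation-major, phase-minor order; the sidecar
#' carries pixel size, PSF FWHM, per-orientation pattern parameters and the
#' noise record, enough to regenerate the stack bit-identically.
#'
#' @param stack A `sim_stack`.
#' @param tiff_path Output TIFF path.
#' @param sidecar_path Output JSON path; default swaps the TIFF extension for
#'   `.json`.
#' @param force Overwrite existing files (default `FALSE`).
#' @return Invisibly, the two paths.
#' @export
write_stack <- function(stack, tiff_path,
                        sidecar_path = sub("\\.tiff?$", ".json", tiff_path),
                        force = FALSE) {
  stopifnot(inherits(stack, "sim_stack"))
  if (identical(sidecar_path, tiff_path)) {
    sidecar_path <- paste0(tiff_path, ".json")
  }
  check_overwrite(tiff_path, force)
  check_overwrite(sidecar_path, force)
  scale <- intensity_scale_for(stack$frames)
  tryCatch(
    tiff::writeTIFF(lapply(stack$frames, function(f) pmax(f, 0) / scale),
                    tiff_path, bits.per.sample = 32L, reduce = FALSE),
    error = function(e) stop_sdrsim(
      sprintf("cannot write '%s': %s", tiff_path, conditionMessage(e)),
      "sdrsim_io_error"))
  meta <- stack_metadata(stack)
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, sidecar_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(tiff = tiff_path, sidecar = sidecar_path))
}

validate_stack_metadata <- function(meta) {
  required <- c("schema_version", "frame_order", "pixel_size_nm",
                "psf_fwhm_nm", "patterns")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop_sdrsim(paste0("sidecar missing field(s): ",
                       paste(missing, collapse = ", ")),
                "sdrsim_metadata_error")
  }
  if (length(meta$patterns) != 3L) {
    stop_sdrsim(sprintf("sidecar must carry 3 pattern records, found %d",
                        length(meta$patterns)), "sdrsim_metadata_error")
  }
  pat_required <- c("orientation_deg", "period_nm", "modulation_depth",
                    "mean_intensity", "initial_phase_rad", "phase_shifts_rad")
  for (d in seq_along(meta$patterns)) {
    missing <- setdiff(pat_required, names(meta$patterns[[d]]))
    if (length(missing)) {
      stop_sdrsim(sprintf("pattern %d missing field(s): %s", d,
                          paste(missing, collapse = ", ")),
                  "sdrsim_metadata_error")
    }
    if (length(unlist(meta$patterns[[d]]$phase_shifts_rad)) != 3L) {
      stop_sdrsim(sprintf("pattern %d: phase_shifts_rad must have length 3", d),
                  "sdrsim_metadata_error")
    }
  }
  invisible(meta)
}

#' Read a raw stack from TIFF plus JSON sidecar
#'
#' @param tiff_path 9-page float TIFF.
#' @param sidecar_path JSON sidecar; default swaps the extension for `.json`.
#' @return A `sim_stack` with frames as floating-point counts and full
#'   metadata attached.
#' @export
read_stack <- function(tiff_path,
                       sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  if (!file.exists(tiff_path)) {
    stop_sdrsim(sprintf("no such file: '%s'", tiff_path), "sdrsim_io_error")
  }
  if (!file.exists(sidecar_path)) {
    stop_sdrsim(sprintf("no such sidecar: '%s'", sidecar_path), "sdrsim_io_error")
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 9L) {
    stop_sdrsim(sprintf("expected a 9-page TIFF, found %d page(s)",
                        length(pages)), "sdrsim_shape_error")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  validate_stack_metadata(meta)
  grid <- grid2d(nrow(pages[[1]]), ncol(pages[[1]]), meta$pixel_size_nm)
  patterns <- lapply(meta$patterns, pattern_from_list)
  noise <- if (is.null(meta$noise)) NULL else
    noise_model(poisson = isTRUE(meta$noise$poisson),
                read_noise_sd = meta$noise$read_noise_sd,
                seed = meta$noise$seed)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  new_sim_stack(
    lapply(pages, function(p) matrix(as.numeric(p) * scale, nrow(p), ncol(p))),
    patterns, gaussian_psf(meta$psf_fwhm_nm), grid, noise)
}

#' Write a scene's ground truth as JSON
#'
#' @param object A `scene_object`.
#' @param path Output JSON path.
#' @param force Overwrite an existing file.
#' @return Invisibly, the path.
#' @export
write_scene_truth <- function(object, path, force = FALSE) {
  stopifnot(inherits(object, "scene_object"))
  check_overwrite(path, force)
  jsonlite::write_json(
    c(object$truth,
      list(n_rows = object$grid$n_rows, n_cols = object$grid$n_cols,
           pixel_size_nm = object$grid$pixel_size_nm)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON
#'
#' @param path Truth JSON written by [write_scene_truth()].
#' @return The truth record as a list; point-like truths gain a tibble
#'   `$centers` with `x_nm`, `y_nm`.
#' @export
read_scene_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(truth$x_nm)) {
    truth$centers <- tibble::tibble(x_nm = truth$x_nm, y_nm = truth$y_nm)
  }
  truth
}

#' Write a reconstruction result as TIFF plus provenance JSON
#'
#' Single-page 32-bit float TIFF; the sidecar records the method, every
#' reconstruction parameter (patterns, PSF, Wiener constant, noise seed) and
#' the software version.
#'
#' @param result A `recon_result`.
#' @param tiff_path Output TIFF path.
#' @param sidecar_path Output JSON path; default swaps the extension.
#' @param force Overwrite existing files.
#' @return Invisibly, the two paths.
#' @export
write_result <- function(result, tiff_path,
                         sidecar_path = sub("\\.tiff?$", ".json", tiff_path),
                         force = FALSE) {
  stopifnot(inherits(result, "recon_result"))
  if (identical(sidecar_path, tiff_path)) {
    sidecar_path <- paste0(tiff_path, ".json")
  }
  check_overwrite(tiff_path, force)
  check_overwrite(sidecar_path, force)
  scale <- intensity_scale_for(list(result$sr_image))
  tryCatch(
    tiff::writeTIFF(pmax(result$sr_image, 0) / scale, tiff_path,
                    bits.per.sample = 32L, reduce = FALSE),
    error = function(e) stop_sdrsim(
      sprintf("cannot write '%s': %s", tiff_path, conditionMessage(e)),
      "sdrsim_io_error"))
  prov <- list(
    schema_version = STACK_SCHEMA_VERSION,
    intensity_scale = scale,
    software = paste0("sdrsim ", utils::packageVersion("sdrsim")),
    method = result$method,
    wiener_w = result$params$wiener_w,
    pad_factor = result$params$pad_factor,
    n_rows = nrow(result$sr_image),
    n_cols = ncol(result$sr_image),
    pixel_size_nm = if (!is.null(result$grid)) result$grid$pixel_size_nm else NULL,
    psf_fwhm_nm = result$params$psf$fwhm_nm,
    patterns = lapply(result$params$patterns, pattern_to_list),
    noise = if (is.null(result$params$noise)) NULL else
      list(poisson = result$params$noise$poisson,
           read_noise_sd = result$params$noise$read_noise_sd,
           seed = result$params$noise$seed)
  )
  jsonlite::write_json(prov, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(tiff = tiff_path, sidecar = sidecar_path))
}

#' Read a reconstruction result written by [write_result()]
#'
#' @param tiff_path Single-page float TIFF.
#' @param sidecar_path Provenance JSON; default swaps the extension.
#' @return List with `image` (numeric matrix, counts), `grid` (when pixel size
#'   is recorded) and `meta` (the provenance record).
#' @export
read_result <- function(tiff_path,
                        sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  if (!file.exists(tiff_path)) {
    stop_sdrsim(sprintf("no such file: '%s'", tiff_path), "sdrsim_io_error")
  }
  img <- tiff::readTIFF(tiff_path)
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else NULL
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  img <- matrix(as.numeric(img) * scale, nrow(img), ncol(img))
  grid <- if (!is.null(meta$pixel_size_nm)) {
    grid2d(nrow(img), ncol(img), meta$pixel_size_nm)
  } else NULL
  list(image = img, grid = grid, meta = meta)
}
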