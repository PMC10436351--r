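#' Write a contrast or intensity image as 32-bit TIFF
#'
#' The image is affinely mapped to `[0, 1]` for storage; the offset and
#' scale, together with an echo of the optical configuration, are written to
#' a YAML sidecar (`<path>_meta.yaml`) so the stored values are
#' reconstructable without the session.
#'
#' @param img Numeric matrix.
#' @param path Output TIFF path.
#' @param config Optional [optical_config()] echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, config = NULL) {
  lo <- min(img)
  hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  suppressWarnings(tiff::writeTIFF((img - lo) / scale, path,
                                   bits.per.sample = 32L, reduce = FALSE))
  meta <- list(offset = lo, scale = scale)
  if (!is.null(config))
    meta$config <- list(wavelength_m = config$wavelength, na = config$na,
                        n_g = config$n_g, n_m = config$n_m,
                        mask_transmission = config$mask_transmission,
                        mask_phase_rad = config$mask_phase,
                        d_px_m = config$d_px, n_pix = config$n_pix)
  yaml::write_yaml(meta, paste0(sub("\\.tiff?$", "", path), "_meta.yaml"))
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @return Numeric matrix with the original values restored.
#' @export
read_image_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(sub("\\.tiff?$", "", path), "_meta.yaml"))
  img <- tiff::readTIFF(path)
  img * meta$scale + meta$offset
}
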