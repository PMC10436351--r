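#' Correlated cover-glass roughness
#'
#' Generates the nanoscopic height map of a microscope cover glass: spatially
#' white uniform noise, low-pass filtered in frequency space to the requested
#' lateral correlation length, and peak-normalized to the requested height
#' amplitude. Typical real coverslips show ~2 nm height variation over
#' ~100 nm lateral scales; the defaults emulate that as a +-0.8 nm bounded
#' map with 100 nm autocorrelation FWHM.
#'
#' @param n_pix Grid size (pixels).
#' @param d_px Pixel pitch (m).
#' @param correlation_length Target autocorrelation FWHM (m); must be at
#'   least `d_px` (the default 100 nm on a 70 nm grid is close to that
#'   resolution limit, i.e. near diffraction-limited speckle).
#' @param amplitude Height bound (m); the map spans `[-amplitude, amplitude]`.
#' @param seed Integer seed; the same seed reproduces the surface bit for bit.
#' @return An object of class `rough_surface` with fields `height` (m),
#'   `correlation_length`, `amplitude`, `d_px`, `seed`.
#' @export
generate_height_map <- function(n_pix = 128L, d_px = 70e-9,
                                correlation_length = 100e-9,
                                amplitude = 0.8e-9, seed = 1L) {
  if (correlation_length < d_px)
    stop("invalid config: correlation length below the grid resolution")
  white <- local_seed(seed, matrix(stats::runif(n_pix^2, -1, 1), n_pix, n_pix))
  if (amplitude == 0) {
    h <- matrix(0, n_pix, n_pix)
  } else {
    # Gaussian spectral filter whose filtered-noise autocorrelation FWHM
    # equals the requested correlation length
    sigma_f <- correlation_length / (2 * sqrt(2 * log(2)) * sqrt(2))
    kr <- k_grids(n_pix, d_px)$kr
    filt <- exp(-kr^2 * sigma_f^2 / 2)
    h <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / n_pix^2
    h <- h / max(abs(h)) * amplitude
  }
  structure(list(height = h, correlation_length = correlation_length,
                 amplitude = amplitude, d_px = d_px, seed = seed),
            class = "rough_surface")
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' A perfectly flat reference surface
#'
#' @param n_pix,d_px Grid geometry.
#' @return A `rough_surface` with zero height everywhere.
#' @export
flat_surface <- function(n_pix = 128L, d_px = 70e-9) {
  generate_height_map(n_pix, d_px, correlation_length = 2 * d_px,
                      amplitude = 0, seed = 0L)
}

#' Phase retardation of the reflected field over a rough surface
#'
#' Converts a height map into the phase map psi of the reflected reference
#' field. The implemented prefactor is the round-trip optical path in glass,
#' `psi = 2 k0 n_g dh`: light reflecting off a locally raised surface travels
#' the extra height twice at the glass index. The additional effective phase
#' picked up by the transmitted (scattering-bound) field can be included with
#' `include_transmission_term = TRUE`, which adds `k0 (n_g - n_m) dh`;
#' it is off by default since its coverslip-phase contribution to protein
#' contrast is not separately constrained.
#'
#' @param surface A [rough_surface()].
#' @param config An [optical_config()] (supplies wavelength and indices).
#' @param include_transmission_term Logical, see above.
#' @return Phase map (rad), linear in the height map.
#' @export
height_to_phase <- function(surface, config,
                            include_transmission_term = FALSE) {
  stopifnot(inherits(surface, "rough_surface"))
  if (nrow(surface$height) != config$n_pix)
    stop("surface and config grids do not match")
  k0 <- 2 * pi / config$wavelength
  pref <- 2 * k0 * config$n_g
  if (include_transmission_term) pref <- pref + k0 * (config$n_g - config$n_m)
  pref * surface$height
}

#' Speckle background image of a rough cover glass
#'
#' Images the reflected reference field of a rough surface through the masked
#' optical system. Because the roughness-induced field components largely
#' fall outside the mask cutoff while the mean (flat) reflection is
#' attenuated, the resulting speckle contrast far exceeds a single-protein
#' signal. Deterministic given the surface. A flat surface reproduces the
#' flat-interface reflectivity exactly.
#'
#' @param surface A [rough_surface()].
#' @param config An [optical_config()] whose grid matches the surface.
#' @param normalize If `TRUE` (default) the image is divided by the expected
#'   flat-interface level so a flat surface maps to 1 everywhere.
#' @return Intensity image (`n_pix x n_pix`).
#' @export
speckle_background <- function(surface, config, normalize = TRUE) {
  grid <- NULL  # the reference path only needs the coarse grid
  bg <- reference_field(config, grid, roughness = surface)
  img <- Mod(bg$field)^2
  if (normalize) img / bg$flat_level else img
}
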