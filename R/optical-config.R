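#' Optical configuration of the simulated mass photometer
#'
#' Bundles every optical parameter that governs field propagation and image
#' formation: illumination wavelength, refractive indices of immersion medium,
#' cover glass and buffer, objective NA and focal length, the partially
#' transmissive back-focal-plane (BFP) attenuation mask, and the sample-space
#' pixel grid. All lengths are in metres.
#'
#' The coordinate conventions used throughout the package: pixel (1,1) sits at
#' the image corner, pixels are half-open intervals, and z is positive going
#' away from the glass into the buffer medium. The nominal focus is the
#' glass-water interface at z = 0.
#'
#' @param wavelength Illumination wavelength (m). Default 445 nm.
#' @param na Numerical aperture of the objective. Default 1.42.
#' @param n_i Refractive index of the immersion medium. Default 1.515 (oil).
#' @param n_g Refractive index of the cover glass. Default 1.515.
#' @param n_m Refractive index of the buffer medium. Default 1.333 (water).
#' @param f_obj Focal length of the objective (m). Default 3 mm.
#' @param mask_transmission Power transmission \eqn{|\tau|^2} of the BFP
#'   attenuation mask (1\% unless stated otherwise).
#' @param mask_phase Phase delay added by the mask (rad). 0 reproduces the
#'   defocus-optimised point-spread-function geometry; pi/2 phase-matches
#'   scattered and reference fields at the nominal focal plane and is the
#'   default for landing-assay movies.
#' @param mask_cutoff_na Radius of the mask expressed as an effective NA.
#'   Default 0.58.
#' @param d_px Sample-space pixel pitch (m). Default 70 nm.
#' @param n_pix Lateral grid size in pixels (square grid). Default 128.
#' @param dz Axial step used by sweeps (m). Default equals `d_px`.
#' @param polarization Either `"circular"` (default; simulated as the average
#'   of azimuthally distributed linear polarizations) or a list
#'   `list(type = "linear", angle = <rad>)`.
#' @param k_convention Where the medium index enters the scattering amplitude:
#'   `"vacuum"` (default) drives the dipole prefactor with the vacuum
#'   wavenumber, `"medium"` with the in-medium wavenumber (a factor
#'   \eqn{n_m^2} larger amplitude). The absolute polarizability scale is
#'   convention-dependent; the default is the convention consistent with the
#'   package's quoted polarizability values.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(d_px = 57e-9, n_pix = 70, mask_phase = 0)
#' cfg
#' @export
optical_config <- function(wavelength = 445e-9,
                           na = 1.42,
                           n_i = 1.515,
                           n_g = 1.515,
                           n_m = 1.333,
                           f_obj = 3e-3,
                           mask_transmission = 0.01,
                           mask_phase = pi / 2,
                           mask_cutoff_na = 0.58,
                           d_px = 70e-9,
                           n_pix = 128L,
                           dz = d_px,
                           polarization = "circular",
                           k_convention = c("vacuum", "medium")) {
  k_convention <- match.arg(k_convention)
  if (!is.list(polarization)) {
    polarization <- match.arg(polarization, c("circular", "linear"))
    polarization <- if (polarization == "circular") list(type = "circular")
                    else list(type = "linear", angle = 0)
  }
  cfg <- structure(list(
    wavelength = wavelength, na = na, n_i = n_i, n_g = n_g, n_m = n_m,
    f_obj = f_obj, mask_transmission = mask_transmission,
    mask_phase = mask_phase, mask_cutoff_na = mask_cutoff_na,
    d_px = d_px, n_pix = as.integer(n_pix), dz = dz,
    polarization = polarization, k_convention = k_convention
  ), class = "optical_config")
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (!(wavelength > 0)) stop("invalid config: wavelength must be > 0")
    if (any(c(n_i, n_g, n_m) <= 0)) stop("invalid config: refractive indices must be > 0")
    if (!(na > 0 && na <= n_i)) stop("invalid config: need 0 < NA <= n_i")
    if (mask_transmission < 0 || mask_transmission > 1)
      stop("invalid config: mask transmission must lie in [0, 1]")
    if (!(mask_cutoff_na < na)) stop("invalid config: mask cutoff NA must be < NA")
    if (!(d_px > 0)) stop("invalid config: pixel pitch must be > 0")
    if (n_pix < 8) stop("invalid config: grid too small")
  })
  invisible(cfg)
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  lambda %.1f nm | NA %.2f (n_i %.3f) | glass %.3f / medium %.3f\n",
              x$wavelength * 1e9, x$na, x$n_i, x$n_g, x$n_m))
  cat(sprintf("  mask |tau|^2 = %.4g, phase %.3f rad, cutoff NA %.2f\n",
              x$mask_transmission, x$mask_phase, x$mask_cutoff_na))
  cat(sprintf("  grid %d x %d px at %.0f nm | f_obj %.1f mm | pol %s\n",
              x$n_pix, x$n_pix, x$d_px * 1e9, x$f_obj * 1e3, x$polarization$type))
  invisible(x)
}

#' Read / write an optical configuration as YAML
#'
#' Configurations are stored with explicit SI units in the key names so that a
#' file is unambiguous without reference to the code.
#'
#' @param path File path.
#' @return `read_optical_config()` returns an `optical_config`;
#'   `write_optical_config()` returns `path` invisibly.
#' @export
read_optical_config <- function(path) {
  y <- yaml::read_yaml(path)
  optical_config(
    wavelength = y$wavelength_m, na = y$na, n_i = y$n_i, n_g = y$n_g,
    n_m = y$n_m, f_obj = y$f_obj_m,
    mask_transmission = y$mask_transmission,
    mask_phase = y$mask_phase_rad, mask_cutoff_na = y$mask_cutoff_na,
    d_px = y$d_px_m, n_pix = y$n_pix,
    polarization = if (identical(y$polarization, "circular")) "circular"
                   else list(type = "linear", angle = y$polarization_angle_rad %||% 0),
    k_convention = y$k_convention %||% "vacuum"
  )
}

#' @rdname read_optical_config
#' @param cfg An `optical_config`.
#' @export
write_optical_config <- function(cfg, path) {
  y <- list(
    wavelength_m = cfg$wavelength, na = cfg$na, n_i = cfg$n_i, n_g = cfg$n_g,
    n_m = cfg$n_m, f_obj_m = cfg$f_obj,
    mask_transmission = cfg$mask_transmission,
    mask_phase_rad = cfg$mask_phase, mask_cutoff_na = cfg$mask_cutoff_na,
    d_px_m = cfg$d_px, n_pix = cfg$n_pix,
    polarization = cfg$polarization$type,
    polarization_angle_rad = cfg$polarization$angle %||% 0,
    k_convention = cfg$k_convention
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
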