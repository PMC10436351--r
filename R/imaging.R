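#' Scatterer response consumed by the imaging engine
#'
#' Wraps the effective scalar scattering strength of a molecule (its excess
#' polarizability projected on the illumination polarization, in cubic
#' angstroms) together with its height above the interface.
#'
#' @param alpha_a3 Effective excess polarizability (A^3, package volume
#'   convention; see [sphere_polarizability()]).
#' @param height Height of the point scatterer above the glass surface (m).
#'   The default 0 is the contact limit used throughout.
#' @return An object of class `scatterer_response`.
#' @export
scatterer_response <- function(alpha_a3, height = 0) {
  stopifnot(is.finite(alpha_a3), height >= 0)
  structure(list(alpha_a3 = alpha_a3, height = height),
            class = "scatterer_response")
}

# single point where the A^3 polarizability convention meets SI field optics
alpha_si <- function(alpha_a3) alpha_a3 * 1e-30

# Padded frequency-space machinery shared by the imaging routines.
# The pad factor is chosen so the pupil diameter is sampled by >= n_pupil
# points, which keeps the mask edge and the interface pattern smooth.
imaging_grid <- function(config, n_pupil = 256L) {
  force(n_pupil)
  n <- config$n_pix
  d <- config$d_px
  lam <- config$wavelength
  np_min <- ceiling(n_pupil * lam / (2 * config$na * d))
  np <- max(4L * n, np_min)
  np <- stats::nextn(np, c(2, 3))          # FFT-friendly size
  k0 <- 2 * pi / lam
  kg <- k0 * config$n_g
  g <- k_grids(np, d)
  s_g <- g$kr / kg
  inband <- g$kr <= k0 * config$na
  incut <- g$kr <= k0 * config$mask_cutoff_na
  c_g <- sqrt(pmax(0, 1 - s_g^2))
  list(np = np, k0 = k0, kg = kg, km = k0 * config$n_m,
       kx = g$kx, ky = g$ky, kr = g$kr,
       s_g = s_g, c_g = c_g, phi = atan2(g$ky, g$kx),
       inband = inband, incut = incut,
       dk = 2 * pi / (np * d))
}

# complex mask values over the padded frequency grid
mask_values <- function(config, grid) {
  m <- matrix(0 + 0i, grid$np, grid$np)
  m[grid$inband] <- 1
  m[grid$incut] <- sqrt(config$mask_transmission) * exp(1i * config$mask_phase)
  m
}

# Scattered-field angular spectrum (glass side, at the nominal focus plane)
# for a dipole driven along the in-plane unit vector (cos beta, sin beta).
# Returns the two transverse image field sheets on the padded k-grid.
#
# The pupil weighting is the energy-conserving aplanatic microscope mapping
# F(theta)/sqrt(cos theta_g); the scattering prefactor follows the config's
# k-convention (vacuum k0 by default).
scattered_spectrum <- function(config, response, grid, beta = 0) {
  k_sc <- if (config$k_convention == "vacuum") grid$k0 else grid$km
  t1 <- 2 * config$n_g / (config$n_g + config$n_m)  # normal-incidence drive
  p <- c(cos(beta), sin(beta), 0)
  pat <- dipole_interface_pattern(grid$s_g, grid$phi, p,
                                  config$n_m, config$n_g,
                                  h = response$height, k0 = grid$k0)
  drive_phase <- exp(1i * grid$km * response$height)
  amp <- 1i / (2 * pi * grid$kg) *
    ifelse(grid$c_g > 0, grid$c_g^(-0.5), 0) *
    (k_sc^2 / (4 * pi)) * alpha_si(response$alpha_a3) * t1 * drive_phase
  ex <- amp * (-pat$e_p * cos(grid$phi) - pat$e_s * sin(grid$phi))
  ey <- amp * (-pat$e_p * sin(grid$phi) + pat$e_s * cos(grid$phi))
  ex[!grid$inband] <- 0
  ey[!grid$inband] <- 0
  list(ex = ex, ey = ey)
}

# One detector-plane complex field from a k-space sheet (padded grid),
# optionally shifted by (x0, y0) metres; cropped to the configured grid.
spectrum_to_image <- function(sheet, grid, config, x0 = 0, y0 = 0,
                              crop = TRUE) {
  if (x0 != 0 || y0 != 0)
    sheet <- sheet * exp(-1i * (grid$kx * x0 + grid$ky * y0))
  img <- stats::fft(sheet, inverse = TRUE) * grid$dk^2
  if (crop) img[seq_len(config$n_pix), seq_len(config$n_pix)] else img
}

# defocus phases for a sample displaced by dz along +z (away from the glass):
# reference reflection picks up 2 k_g dz, the scattered spectrum
# k_g dz (1 + cos theta_g)
defocus_factors <- function(grid, dz) {
  list(ref = exp(2i * grid$kg * dz),
       sca = exp(1i * grid$kg * dz * (1 + grid$c_g)))
}

pol_angles <- function(config, n_az = 4L) {
  if (config$polarization$type == "circular") (seq_len(n_az) - 1) * pi / n_az
  else config$polarization$angle
}

#' Detector image of a point scatterer at the interface
#'
#' Renders the interferometric intensity image of a single point scatterer on
#' (or above) the cover glass under widefield plane-wave illumination: the
#' reference is the Fresnel reflection of the illumination at the glass-water
#' interface, attenuated and phase-shifted by the BFP mask; the scattered
#' field is the dipole-at-interface angular spectrum (including the
#' supercritical near-field components and the water-path aberration phase of
#' an elevated emitter), band-limited by the objective NA, masked, and
#' brought to the detector with the energy-conserving aplanatic pupil
#' weighting. Circular polarization is simulated as the average over
#' azimuthally distributed linear polarizations.
#'
#' @param config An [optical_config()].
#' @param response A [scatterer_response()], or `NULL`/0-strength for the
#'   pure reference image.
#' @param z_sample Axial displacement of the sample from nominal focus (m).
#' @param roughness Optional [rough_surface()]; when supplied the reference
#'   is the speckled reflection of the rough glass instead of a uniform
#'   plane wave.
#' @param n_az Number of azimuthal polarizations averaged for circular
#'   illumination.
#' @param position Lateral scatterer position `c(x, y)` in metres from the
#'   image corner; defaults to the grid centre.
#' @param n_pupil Minimum samples across the pupil diameter (controls the
#'   frequency-space padding).
#' @return A list with `i_det` (intensity image), `i_bkg` (reference-only
#'   image), and `contrast` (their ratiometric difference), each
#'   `n_pix x n_pix`.
#' @export
image_point_source <- function(config, response, z_sample = 0,
                               roughness = NULL, n_az = 4L,
                               position = NULL, n_pupil = 256L) {
  point_imager(config, response, roughness, n_az, position, n_pupil)(z_sample)
}

# Closure rendering the scene at any defocus without recomputing the
# z-independent spectra; used by image_point_source and the axial sweep.
point_imager <- function(config, response, roughness = NULL, n_az = 4L,
                         position = NULL, n_pupil = 256L) {
  grid <- imaging_grid(config, n_pupil)
  if (is.null(position))
    position <- rep((config$n_pix / 2) * config$d_px, 2)
  if (any(position < 0 | position > config$n_pix * config$d_px))
    stop("scatterer position outside the field of view")
  zero_response <- is.null(response) || response$alpha_a3 == 0
  bg <- reference_field(config, grid, roughness) # complex n_pix^2 image
  if (zero_response) {
    return(function(z_sample) {
      i_bkg <- Mod(bg$field)^2
      list(i_det = i_bkg, i_bkg = i_bkg,
           contrast = matrix(0, config$n_pix, config$n_pix))
    })
  }
  betas <- pol_angles(config, n_az)
  mv <- mask_values(config, grid)
  ramp <- exp(-1i * (grid$kx * position[1] + grid$ky * position[2]))
  sheets <- lapply(betas, function(b) {
    sp <- scattered_spectrum(config, response, grid, beta = b)
    list(ex = sp$ex * mv * ramp, ey = sp$ey * mv * ramp)
  })
  cr <- seq_len(config$n_pix)
  function(z_sample) {
    df <- defocus_factors(grid, z_sample)
    e_ref_img <- bg$field * df$ref
    i_det <- 0
    for (i in seq_along(betas)) {
      b <- betas[i]
      ex <- (stats::fft(sheets[[i]]$ex * df$sca, inverse = TRUE) *
               grid$dk^2)[cr, cr]
      ey <- (stats::fft(sheets[[i]]$ey * df$sca, inverse = TRUE) *
               grid$dk^2)[cr, cr]
      # reference is co-polarized with the illumination at angle b
      i_det <- i_det + Mod(e_ref_img * cos(b) + ex)^2 +
                       Mod(e_ref_img * sin(b) + ey)^2
    }
    i_det <- i_det / length(betas)
    i_bkg <- Mod(e_ref_img)^2
    list(i_det = i_det, i_bkg = i_bkg,
         contrast = ratiometric_contrast(i_det, i_bkg))
  }
}

# Imaged reference field (complex, cropped): uniform for flat glass, speckled
# for a rough surface. The DC (and any component inside the mask cutoff) is
# attenuated and phase shifted by the mask; roughness components outside the
# cutoff pass unattenuated, which is what makes the speckle contrast large.
reference_field <- function(config, grid, roughness = NULL) {
  r0 <- interface_reflectivity(config)
  maskc <- sqrt(config$mask_transmission) * exp(1i * config$mask_phase)
  if (is.null(roughness)) {
    f <- matrix(r0 * maskc, config$n_pix, config$n_pix)
    return(list(field = f, flat_level = Mod(r0 * maskc)^2))
  }
  # the surface is generated with periodic spectral filtering, so masking it
  # on its own (periodic) grid is seamless and avoids padding edge artefacts
  psi <- height_to_phase(roughness, config)
  e_samp <- r0 * exp(1i * psi)                       # n_pix x n_pix
  n <- config$n_pix
  k0 <- 2 * pi / config$wavelength
  kr <- k_grids(n, config$d_px)$kr
  m <- matrix(0 + 0i, n, n)
  m[kr <= k0 * config$na] <- 1
  m[kr <= k0 * config$mask_cutoff_na] <- maskc
  sp <- stats::fft(e_samp) * m
  img <- stats::fft(sp, inverse = TRUE) / length(sp)
  list(field = img, flat_level = Mod(r0 * maskc)^2)
}

#' Ratiometric contrast of a detected image against its background
#'
#' Per-pixel relative difference `(i_det - i_bkg)/i_bkg`, the primary
#' observable of mass photometry. In the small-signal regime it equals
#' `2 (|s|/|r|) cos(phi) + (|s|/|r|)^2` for scattered and reference
#' amplitudes `|s|`, `|r|` with phase difference `phi`.
#'
#' @param i_det,i_bkg Intensity images of equal size; `i_bkg` must be
#'   strictly positive.
#' @return The contrast map.
#' @export
ratiometric_contrast <- function(i_det, i_bkg) {
  if (!identical(dim(i_det), dim(i_bkg)))
    stop("intensity images must share a grid")
  if (any(i_bkg <= 0))
    stop("background contains non-positive pixels; contrast undefined")
  (i_det - i_bkg) / i_bkg
}

#' Contrast as a function of axial sample displacement
#'
#' Sweeps the sample position along the optical axis, records the extremal
#' ratiometric contrast of each rendered image, and returns the displacement
#' that maximizes the contrast magnitude. With a zero-phase mask the optimum
#' lies ~190 nm from nominal focus (Gouy-phase tuning); with a pi/2 mask the
#' optimum returns to the nominal focal plane. After the coarse sweep the
#' optimum is refined on a 10x finer local grid.
#'
#' @param config An [optical_config()].
#' @param response A [scatterer_response()].
#' @param z_range Length-2 numeric, sweep interval (m), bracketing focus.
#' @param dz Coarse step (m); defaults to `config$dz`.
#' @param refine Logical, refine around the coarse optimum (default TRUE).
#' @param n_az Azimuthal polarization count for circular illumination.
#' @return A list with `z_opt` (m), `c_opt` (signed contrast at the optimum),
#'   and `profile`, a data.frame of `z` and extremal `contrast` per slice.
#' @export
axial_contrast_sweep <- function(config, response, z_range, dz = config$dz,
                                 refine = TRUE, n_az = 4L) {
  if (length(z_range) != 2 || diff(z_range) <= 0)
    stop("z_range must be an increasing length-2 interval")
  zs <- seq(z_range[1], z_range[2], by = dz)
  imager <- point_imager(config, response, n_az = n_az)
  ext <- function(z) {
    cmap <- imager(z)$contrast
    cmap[which.max(abs(cmap))]
  }
  prof <- vapply(zs, ext, numeric(1))
  i <- which.max(abs(prof))
  z_opt <- zs[i]; c_opt <- prof[i]
  if (refine) {
    zf <- seq(max(z_range[1], z_opt - dz), min(z_range[2], z_opt + dz),
              by = dz / 10)
    pf <- vapply(zf, ext, numeric(1))
    j <- which.max(abs(pf))
    z_opt <- zf[j]; c_opt <- pf[j]
  }
  list(z_opt = z_opt, c_opt = c_opt,
       profile = data.frame(z = zs, contrast = prof))
}
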