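#' Parameter set of the analytic photon budget
#'
#' Every quantity entering the closed-form signal-to-noise chain, in SI base
#' units unless noted. The defaults are the standard mass-photometry
#' operating point: 0.1 MW/cm^2 illumination, 100 ms effective exposure,
#' 445 nm, a 1.42 NA oil objective with 3 mm focal length, 2\% mask
#' transmission, 80 nm effective pixels and a 66 kDa analyte.
#'
#' `mu`, `gamma` and `a_bfp` may be given explicitly (e.g. the rounded
#' values quoted alongside the budget: mu 0.40, gamma 1.58, A_BFP 50 mm^2) or
#' left `NULL` to be computed by [derived_factors()].
#'
#' @param i_illu Illumination intensity (W/m^2).
#' @param dt Effective exposure time per ratiometric half-stack (s).
#' @param wavelength Wavelength (m).
#' @param ot Optical throughput (0..1).
#' @param qe Detector quantum efficiency (0..1).
#' @param r2 Interface power reflectivity `|r|^2`.
#' @param tau2 Mask power transmission `|tau|^2`.
#' @param f_obj Objective focal length (m).
#' @param d_px Effective pixel size in sample space (m).
#' @param n_m,n_i,n_g Buffer, immersion and glass refractive indices.
#' @param na Numerical aperture.
#' @param dalpha Polarizability change per mass (A^3/kDa).
#' @param m Analyte mass (kDa).
#' @param sigma_exc Excess dynamic background expressed as the mass of a
#'   protein with equivalent contrast (kDa); 0 for shot-noise-limited.
#' @param mu,gamma,a_bfp Optional overrides of the derived factors
#'   (collection efficiency, interface enhancement, accessible BFP area m^2).
#' @return An object of class `snr_parameters`.
#' @export
snr_parameters <- function(i_illu = 1e9, dt = 0.1, wavelength = 445e-9,
                           ot = 0.8, qe = 0.70, r2 = 0.004, tau2 = 0.02,
                           f_obj = 3e-3, d_px = 80e-9,
                           n_m = 1.333, n_i = 1.515, n_g = 1.515, na = 1.42,
                           dalpha = 724, m = 66, sigma_exc = 0,
                           mu = NULL, gamma = NULL, a_bfp = NULL) {
  p <- structure(list(i_illu = i_illu, dt = dt, wavelength = wavelength,
                      ot = ot, qe = qe, r2 = r2, tau2 = tau2,
                      f_obj = f_obj, d_px = d_px,
                      n_m = n_m, n_i = n_i, n_g = n_g, na = na,
                      dalpha = dalpha, m = m, sigma_exc = sigma_exc,
                      mu = mu, gamma = gamma, a_bfp = a_bfp),
                 class = "snr_parameters")
  frac <- c(ot = ot, qe = qe, r2 = r2, tau2 = tau2)
  if (any(frac < 0 | frac > 1))
    stop("OT, QE, |r|^2 and |tau|^2 must lie in [0, 1]")
  if (any(c(i_illu, dt, wavelength, f_obj, d_px, dalpha) < 0))
    stop("negative physical parameter")
  p
}

planck_h <- 6.62607015e-34
light_c <- 2.99792458e8

#' Derived collection factors of the photon budget
#'
#' Collection efficiency `mu = asin(min(NA/n_i, 1))/pi`, accessible BFP area
#' `A_BFP = pi f_obj^2 (n_i n_m / n_g)^2` (limited by the water-side critical
#' angle), and the interface scattering enhancement gamma from
#' [gamma_interface()].
#'
#' @param p An [snr_parameters()].
#' @param gamma_method Passed to [gamma_interface()] (`"model"` or
#'   `"table"`).
#' @return A list with `mu`, `a_bfp` (m^2) and `gamma`. Values supplied
#'   explicitly in `p` are passed through unchanged.
#' @examples
#' derived_factors(snr_parameters())$a_bfp * 1e6   # ~50 mm^2
#' @export
derived_factors <- function(p, gamma_method = "model") {
  stopifnot(inherits(p, "snr_parameters"))
  list(
    mu = p$mu %||% (asin(min(p$na / p$n_i, 1)) / pi),
    a_bfp = p$a_bfp %||% (pi * p$f_obj^2 * (p$n_i * p$n_m / p$n_g)^2),
    gamma = p$gamma %||% gamma_interface(p$na, p$n_m, p$n_g, p$n_i,
                                         method = gamma_method)
  )
}

photon_fluence <- function(p) p$i_illu * p$dt * p$wavelength / (planck_h * light_c)

#' Detected scattered photons per pixel and exposure
#'
#' Photon budget of the scattered arm: the illumination photon fluence times
#' the Rayleigh scattering cross-section `k_m^4 (dalpha m)^2 / 6 pi` of the
#' analyte, the optical throughput and quantum efficiency, the collection
#' factors `mu * gamma`, and the fraction of the collected light landing on
#' the brightest pixel, `A_BFP d_px^2 / (lambda^2 f_obj^2)`. Linear in
#' illumination dose and quadratic in `m * dalpha`.
#'
#' @param p An [snr_parameters()].
#' @return Expected scattered photons per pixel per exposure.
#' @export
scattered_photons <- function(p) {
  d <- derived_factors(p)
  k_m <- 2 * pi * p$n_m / p$wavelength
  sigma <- k_m^4 * (p$dalpha * 1e-30 * p$m)^2 / (6 * pi)
  photon_fluence(p) * p$ot * p$qe * d$mu * d$gamma * sigma *
    d$a_bfp * p$d_px^2 / (p$wavelength^2 * p$f_obj^2)
}

#' Detected reflected photons per pixel and exposure
#'
#' Reference-arm budget: photon fluence times interface reflectivity, mask
#' transmission, throughput, quantum efficiency and pixel area.
#'
#' @param p An [snr_parameters()].
#' @return Expected reflected photons per pixel per exposure.
#' @export
reflected_photons <- function(p) {
  photon_fluence(p) * p$ot * p$qe * p$r2 * p$tau2 * p$d_px^2
}

#' Shot-noise-limited SNR of the ratiometric contrast
#'
#' The interferometric signal amplitude is `2 sqrt(N_sca N_ref)` against the
#' shot noise `sqrt(2 N_ref)` of the two compared frame stacks, so
#' `SNR = sqrt(2 N_sca)`: a factor 2 from the interferometric nature of the
#' signal and a factor `1/sqrt(2)` from the ratiometric frame comparison.
#' Linear in mass, proportional to `sqrt(i_illu * dt)`.
#'
#' @param p An [snr_parameters()].
#' @return Dimensionless SNR.
#' @examples
#' shot_noise_snr(snr_parameters(mu = 0.40, gamma = 1.58, a_bfp = 50e-6)) # ~21
#' @export
shot_noise_snr <- function(p) {
  if (reflected_photons(p) <= 0)
    stop("zero reflected photons: ratiometric contrast undefined")
  sqrt(2 * scattered_photons(p))
}

#' Smallest detectable mass at a given SNR threshold
#'
#' Inverts the SNR relation for mass: since SNR is linear in `m`,
#' `m_q = m * q / SNR(m)`.
#'
#' @param p An [snr_parameters()].
#' @param q SNR threshold (default 3).
#' @return Detection-limit mass (kDa).
#' @export
detection_limit_mass <- function(p, q = 3) {
  stopifnot(q > 0)
  p$m * q / shot_noise_snr(p)
}

#' Quantum Cramer-Rao bound on mass resolution
#'
#' The photon-statistics floor on the mass uncertainty of a single
#' measurement, `sigma_m = m / (sqrt(2) SNR(m))`. Equivalently (the
#' SNR-equivalent-mass identity) the highest attainable resolution equals the
#' mass that reaches an SNR of `1/sqrt(2)` in the shot-noise limit, so
#' `qcrlb_resolution(p) == detection_limit_mass(p, 1/sqrt(2))`.
#'
#' @param p An [snr_parameters()].
#' @return Mass resolution (kDa).
#' @export
qcrlb_resolution <- function(p) {
  p$m / (sqrt(2) * shot_noise_snr(p))
}

#' SNR including the excess dynamic background
#'
#' The dynamic, speckle-like background with contrast equivalent to a
#' `sigma_exc`-kDa protein is added in quadrature to the shot-noise variance.
#' In contrast units the excess floor is mass-equivalent, so
#' `1/SNR_exc^2 = 1/SNR_shot^2 + (sigma_exc/m)^2`: shot-noise-limited
#' performance is recovered for `sigma_exc = 0`, and for unbounded photon
#' flux the SNR saturates at the finite ceiling `m / sigma_exc`.
#'
#' @param p An [snr_parameters()] with its `sigma_exc` field set (kDa).
#' @return Dimensionless SNR.
#' @export
snr_with_excess <- function(p) {
  stopifnot(p$sigma_exc >= 0)
  s <- shot_noise_snr(p)
  if (p$sigma_exc == 0) return(s)
  1 / sqrt(1 / s^2 + (p$sigma_exc / p$m)^2)
}

#' Simplified SNR constant
#'
#' Collapses the full budget into `SNR = kappa * m * sqrt(i_illu * dt /
#' lambda^5)`. The constant is computed from the current parameter set at
#' call time (never hard-coded), so a unit error anywhere in the chain
#' surfaces immediately as a mismatch with the full evaluation.
#'
#' @param p An [snr_parameters()].
#' @return The constant kappa.
#' @export
kappa_constant <- function(p) {
  shot_noise_snr(p) / (p$m * sqrt(p$i_illu * p$dt / p$wavelength^5))
}

#' Performance maps over illumination intensity and exposure time
#'
#' Vectorized evaluation of SNR (with and without excess noise), detection
#' limit `m_q` and mass resolution over a grid of operating points.
#'
#' @param p An [snr_parameters()] template.
#' @param i_illu Vector of illumination intensities (W/m^2).
#' @param dt Vector of exposure times (s).
#' @param q SNR threshold for the detection-limit map.
#' @return A list of matrices (`length(i_illu) x length(dt)`): `snr`,
#'   `snr_exc`, `m_q`, `sigma_m`, plus the axes.
#' @export
performance_maps <- function(p, i_illu, dt, q = 3) {
  eval_at <- function(ii, tt, fun) {
    pp <- p; pp$i_illu <- ii; pp$dt <- tt
    fun(pp)
  }
  grid_eval <- function(fun)
    outer(i_illu, dt, Vectorize(function(ii, tt) eval_at(ii, tt, fun)))
  list(i_illu = i_illu, dt = dt,
       snr = grid_eval(shot_noise_snr),
       snr_exc = grid_eval(snr_with_excess),
       m_q = grid_eval(function(pp) detection_limit_mass(pp, q)),
       sigma_m = grid_eval(qcrlb_resolution))
}
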