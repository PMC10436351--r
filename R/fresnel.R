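#' Fresnel coefficients of the glass-water interface
#'
#' Amplitude reflection and transmission coefficients for the cover-glass /
#' buffer interface, per incidence angle and polarization. `r` and `t1` are
#' for light incident from the glass side (illumination and reference
#' reflection), `t2` for light incident from the water side (the scattered
#' field returning to the objective). Beyond the critical angle of the water
#' side, transmission is evanescent and the coefficients are complex.
#'
#' @param config An [optical_config()].
#' @param angles Incidence angles (rad) in the glass, in `[0, pi/2)`.
#' @return A list of class `interface_coefficients` with per-angle complex
#'   vectors `r_s`, `r_p` (glass-side reflection), `t1_s`, `t1_p`
#'   (glass to water), `t2_s`, `t2_p` (water to glass, at the water-side angle
#'   conjugate to each glass-side angle), and the `angles` grid.
#' @examples
#' co <- fresnel_interface(optical_config(), 0)
#' Mod(co$r_s)^2   # ~0.004 for 1.515 / 1.333
#' @export
fresnel_interface <- function(config, angles) {
  if (any(angles < 0 | angles >= pi / 2)) stop("angles must lie in [0, pi/2)")
  n1 <- config$n_g
  n2 <- config$n_m
  if (n1 <= 0 || n2 <= 0) stop("invalid config: non-physical refractive index")
  c1 <- cos(angles)
  s2 <- n1 / n2 * sin(angles)                 # Snell, glass -> water
  c2 <- sqrt(as.complex(1 - s2^2))            # evanescent beyond critical angle
  r_s <- (n1 * c1 - n2 * c2) / (n1 * c1 + n2 * c2)
  r_p <- (n2 * c1 - n1 * c2) / (n2 * c1 + n1 * c2)
  t1_s <- 2 * n1 * c1 / (n1 * c1 + n2 * c2)
  t1_p <- 2 * n1 * c1 / (n2 * c1 + n1 * c2)
  # water -> glass at the conjugate angle (reciprocal path of the scattered field)
  t2_s <- 2 * n2 * c2 / (n2 * c2 + n1 * c1)
  t2_p <- 2 * n2 * c2 / (n1 * c2 + n2 * c1)
  structure(list(angles = angles,
                 r_s = drop_imag(r_s), r_p = drop_imag(r_p),
                 t1_s = drop_imag(t1_s), t1_p = drop_imag(t1_p),
                 t2_s = drop_imag(t2_s), t2_p = drop_imag(t2_p)),
            class = "interface_coefficients")
}

# keep coefficients real when the imaginary part is pure round-off
drop_imag <- function(z, tol = 1e-14) {
  if (all(abs(Im(z)) <= tol * pmax(1, abs(Re(z))))) Re(z) else z
}

#' Normal-incidence field reflectivity of the interface
#'
#' @param config An [optical_config()].
#' @return The real amplitude reflection coefficient
#'   \eqn{r = (n_g - n_m)/(n_g + n_m)}.
#' @export
interface_reflectivity <- function(config) {
  (config$n_g - config$n_m) / (config$n_g + config$n_m)
}
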