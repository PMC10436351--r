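#' Complex field maps on the lateral grid
#'
#' A `field_map` holds one complex amplitude sheet per transverse polarization
#' component, sampled on the square lateral grid of an [optical_config()],
#' together with the plane it lives in (`"sample"`, `"bfp"` or `"detector"`)
#' and its axial offset.
#'
#' @param ex,ey Complex matrices (the y sheet may be `NULL` for scalar work).
#' @param config The governing [optical_config()].
#' @param plane One of `"sample"`, `"bfp"`, `"detector"`.
#' @param z Axial offset of the plane (m).
#' @return An object of class `field_map`.
#' @export
field_map <- function(ex, ey = NULL, config, plane = "sample", z = 0) {
  plane <- match.arg(plane, c("sample", "bfp", "detector"))
  ex <- as_complex_matrix(ex)
  if (!is.null(ey)) {
    ey <- as_complex_matrix(ey)
    if (!identical(dim(ex), dim(ey))) stop("ex and ey must share a grid")
  }
  if (!all(is.finite(Re(ex))) || !all(is.finite(Im(ex))))
    stop("field contains non-finite values")
  structure(list(ex = ex, ey = ey, config = config, plane = plane, z = z),
            class = "field_map")
}

as_complex_matrix <- function(m) {
  if (!is.matrix(m)) stop("field sheets must be matrices")
  storage.mode(m) <- "complex"
  m
}

#' Optical power carried by a field map
#'
#' Sum of `|E|^2` over pixels and polarization sheets times the pixel area.
#' Used by the Parseval conservation checks of [propagate()].
#'
#' @param field A [field_map()].
#' @return Scalar power (arbitrary units consistent across the package).
#' @export
field_power <- function(field) {
  p <- sum(Mod(field$ex)^2)
  if (!is.null(field$ey)) p <- p + sum(Mod(field$ey)^2)
  p * field$config$d_px^2
}

# centred FFT frequency grid (rad/m) for an n-point axis with pitch d
k_axis <- function(n, d) {
  2 * pi * c(0:(n %/% 2 - 1), -(n - n %/% 2):-1) / (n * d)
}

k_grids <- function(n, d) {
  kx <- k_axis(n, d)
  kxm <- matrix(kx, n, n)
  list(kx = kxm, ky = t(kxm), kr = sqrt(kxm^2 + t(kxm)^2))
}

#' Angular-spectrum propagation of a field map
#'
#' Applies the exact angular-spectrum phase `exp(i kz d)` per spatial
#' frequency, with `kz = sqrt((k0 n)^2 - kr^2)`. Evanescent components decay
#' for either sign of `distance` (the operator is kept contractive; backward
#' amplification of evanescent waves is never applied). Propagation distances
#' whose steepest propagating ray would walk beyond half the field of view are
#' refused with a diagnostic, since the periodic FFT grid would wrap the
#' energy around.
#'
#' @param field A [field_map()] in the `"sample"` or `"detector"` plane.
#' @param distance Propagation distance (m); positive moves along +z.
#' @param index Refractive index of the traversed medium.
#' @return The propagated [field_map()] with updated `z`.
#' @export
propagate <- function(field, distance, index) {
  stopifnot(inherits(field, "field_map"))
  if (distance == 0) return(field)
  n <- nrow(field$ex)
  d <- field$config$d_px
  k <- 2 * pi * index / field$config$wavelength
  g <- k_grids(n, d)

  # aliasing guard from the actual spectral support of the field
  sup <- spectral_support(field, g$kr, k)
  if (sup$tan_max * abs(distance) > n * d / 2) {
    stop(sprintf(paste0("propagation over %.3g m would wrap around: steepest ",
                        "propagating component (%.1f deg) walks %.3g m laterally, ",
                        "more than half the %.3g m field of view"),
                 distance, atan(sup$tan_max) * 180 / pi,
                 sup$tan_max * abs(distance), n * d))
  }

  kz2 <- k^2 - g$kr^2
  prop_band <- kz2 > 0
  kz <- sqrt(abs(kz2))
  phase <- matrix(0i, n, n)
  phase[prop_band] <- 1i * kz[prop_band] * distance
  phase[!prop_band] <- -kz[!prop_band] * abs(distance)   # decay both ways
  h <- exp(phase)
  tf <- function(e) {
    if (is.null(e)) return(NULL)
    stats::fft(stats::fft(e) * h, inverse = TRUE) / length(e)
  }
  out <- field
  out$ex <- tf(field$ex)
  out$ey <- tf(field$ey)
  out$z <- field$z + distance
  out
}

# radius containing 99.9% of the spectral energy; the walk-off estimate caps
# the ray angle at 80 deg so a vanishing near-grazing tail cannot veto an
# otherwise safe propagation
spectral_support <- function(field, kr, k, energy_frac = 0.999) {
  spec <- Mod(stats::fft(field$ex))^2
  if (!is.null(field$ey)) spec <- spec + Mod(stats::fft(field$ey))^2
  o <- order(kr)
  cum <- cumsum(spec[o])
  krmax <- kr[o][which(cum >= energy_frac * cum[length(cum)])[1]]
  s <- min(krmax / k, sin(80 * pi / 180))
  list(kr_max = krmax, tan_max = s / sqrt(1 - s^2))
}

#' Transform a sample-plane field to the back focal plane
#'
#' The BFP field is the angular spectrum of the sample-plane field, sampled
#' uniformly in pupil coordinates `kr / k0` (NA units). A chirp-z transform
#' zooms into the pupil so that the mask edge is finely resolved regardless
#' of the image-grid sampling; the default resolution places at least 256
#' samples across the pupil diameter.
#'
#' @param field A sample-plane [field_map()].
#' @param n_pupil Number of samples across the pupil diameter (default 256).
#' @return A `field_map` in the `"bfp"` plane whose grid spans NA in
#'   `[-na, na]` on both axes; the NA axis is stored as attribute `na_axis`.
#' @export
to_bfp <- function(field, n_pupil = 256L) {
  stopifnot(inherits(field, "field_map"))
  if (field$plane == "bfp") return(field)
  cfg <- field$config
  n <- nrow(field$ex)
  k0 <- 2 * pi / cfg$wavelength
  # target pupil frequencies: f = k/(2 pi) in cycles/m, spanning +- na/lambda
  f_max <- cfg$na / cfg$wavelength
  df <- 2 * f_max / (n_pupil - 1)
  tf <- function(e) {
    if (is.null(e)) return(NULL)
    czt2(e, m = n_pupil, f0 = -f_max, df = df, d = cfg$d_px)
  }
  out <- field
  out$ex <- tf(field$ex)
  out$ey <- tf(field$ey)
  out$plane <- "bfp"
  attr(out, "na_axis") <- (seq_len(n_pupil) - 1) * df * cfg$wavelength - cfg$na
  class(out) <- "field_map"
  out
}

#' Apply the BFP attenuation mask to a BFP-plane field
#'
#' Inside the mask cutoff the amplitude is scaled by `sqrt(|tau|^2)` and
#' phase-shifted by the configured mask phase; outside the cutoff the field is
#' untouched.
#'
#' @param field A `"bfp"`-plane [field_map()] produced by [to_bfp()].
#' @param config An [optical_config()] supplying the mask parameters.
#' @return The masked `field_map`.
#' @export
apply_bfp_mask <- function(field, config) {
  stopifnot(inherits(field, "field_map"))
  if (field$plane != "bfp")
    stop("apply_bfp_mask expects a field in the BFP plane (see to_bfp())")
  na_axis <- attr(field, "na_axis")
  if (is.null(na_axis)) stop("BFP field lacks its NA axis")
  nx <- matrix(na_axis, length(na_axis), length(na_axis))
  rho <- sqrt(nx^2 + t(nx)^2)
  m <- ifelse(rho <= config$mask_cutoff_na,
              sqrt(config$mask_transmission) * exp(1i * config$mask_phase), 1)
  out <- field
  out$ex <- field$ex * m
  if (!is.null(field$ey)) out$ey <- field$ey * m
  out
}

#' Chirp-z (zoom) discrete Fourier transform
#'
#' One-dimensional Bluestein chirp-z transform evaluating
#' `X_j = sum_n x_n exp(-2 pi i f_j n d)` on the arbitrary uniform frequency
#' grid `f_j = f0 + j df`, and its separable two-dimensional version `czt2()`.
#' Used to sample the objective pupil more finely than the FFT grid of the
#' image allows.
#'
#' @param x Complex vector (or matrix for `czt2`).
#' @param m Number of output frequencies.
#' @param f0 First output frequency (cycles per sample-spacing unit when
#'   `d = 1`; cycles/m for sample pitch `d`).
#' @param df Output frequency step.
#' @param d Sample pitch of `x`.
#' @return Complex vector of length `m` (matrix `m x m` for `czt2`).
#' @export
czt <- function(x, m, f0, df, d = 1) {
  n <- length(x)
  w <- exp(-2i * pi * df * d)        # ratio between successive output points
  a <- exp(-2i * pi * f0 * d)        # starting point on the unit circle
  # Bluestein: X_j = w^{j^2/2} sum_n [x_n a^{-n... } w^{n^2/2}] w^{-(j-n)^2/2}
  nfft <- stats::nextn(n + m - 1, 2)
  # w^{k^2/2} = exp(-i pi df d k^2)
  wk2 <- exp(-1i * pi * df * d * (seq_len(max(n, m)) - 1)^2)
  xx <- x * a^(seq_len(n) - 1) * wk2[seq_len(n)]
  yy <- c(Conj(wk2[seq_len(m)]), rep(0, nfft - n - m + 1),
          Conj(rev(wk2[seq(2, n)])))
  fx <- stats::fft(c(xx, rep(0, nfft - n)))
  fy <- stats::fft(yy)
  conv <- stats::fft(fx * fy, inverse = TRUE) / nfft
  conv[seq_len(m)] * wk2[seq_len(m)]
}

#' @rdname czt
#' @export
czt2 <- function(x, m, f0, df, d = 1) {
  tmp <- apply(x, 2, czt, m = m, f0 = f0, df = df, d = d)      # over rows dim
  t(apply(t(tmp), 2, czt, m = m, f0 = f0, df = df, d = d))
}
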