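test_that("zero-distance propagation is the identity", {
  cfg <- optical_config(n_pix = 32)
  f <- gaussian_field(cfg)
  expect_identical(propagate(f, 0, cfg$n_m)$ex, f$ex)
})

test_that("propagation conserves power (Parseval) for band-limited fields", {
  cfg <- optical_config(n_pix = 64)
  f <- gaussian_field(cfg)
  p0 <- field_power(f)
  for (d in c(1e-6, -2e-6, 2.5e-6)) {
    p1 <- field_power(propagate(f, d, cfg$n_m))
    expect_lt(abs(p1 - p0) / p0, 1e-9)
  }
})

test_that("round-trip propagation recovers the input field", {
  cfg <- optical_config(n_pix = 64)
  f <- gaussian_field(cfg)
  g <- propagate(propagate(f, 3e-6, cfg$n_m), -3e-6, cfg$n_m)
  expect_lt(max(Mod(g$ex - f$ex)) / max(Mod(f$ex)), 1e-10)
})

test_that("an oblique plane wave advances by the closed-form phase", {
  cfg <- optical_config(n_pix = 64)
  n <- cfg$n_pix
  k <- 2 * pi * cfg$n_m / cfg$wavelength
  # plane wave along a grid-commensurate frequency
  m_cyc <- 5
  kx <- 2 * pi * m_cyc / (n * cfg$d_px)
  theta <- asin(kx / k)
  x <- (seq_len(n) - 1) * cfg$d_px
  pw <- field_map(outer(exp(1i * kx * x), rep(1, n)), config = cfg)
  d <- 2e-6
  out <- propagate(pw, d, cfg$n_m)
  expected <- pw$ex * exp(1i * k * cos(theta) * d)
  expect_lt(max(Mod(out$ex - expected)), 1e-9)
})

test_that("wrap-around-inducing distances are refused with a diagnostic", {
  cfg <- optical_config(n_pix = 32)
  # a tightly focused spot has steep angular content
  f <- gaussian_field(cfg, waist = 1.5 * cfg$d_px, band_limit = NULL)
  expect_error(propagate(f, 1e-3, cfg$n_m), "wrap")
})

test_that("power never increases through evanescent-carrying propagation", {
  cfg <- optical_config(n_pix = 64)
  f <- gaussian_field(cfg, waist = 1.5 * cfg$d_px, band_limit = NULL)
  p0 <- field_power(f)
  p1 <- field_power(propagate(f, 1e-7, cfg$n_m))
  expect_lte(p1, p0 * (1 + 1e-12))
  expect_lt(p1, p0)   # evanescent components actually decayed
})

test_that("chirp-z transform agrees with the FFT on the FFT grid", {
  set.seed(1)
  x <- complex(real = rnorm(32), imaginary = rnorm(32))
  # FFT frequencies j/(n d), j = 0..n-1
  got <- czt(x, m = 32, f0 = 0, df = 1 / 32, d = 1)
  expect_equal(got, stats::fft(x), tolerance = 1e-10)
})

test_that("BFP mask contract: transparency, attenuation, phase", {
  cfg <- optical_config(n_pix = 32, mask_transmission = 1, mask_phase = 0)
  f <- to_bfp(gaussian_field(cfg), n_pupil = 64)
  expect_equal(apply_bfp_mask(f, cfg)$ex, f$ex, tolerance = 1e-12)

  # field entirely inside the cutoff: power x 0.01, amplitude x 0.1 i
  cfg2 <- optical_config(n_pix = 32, mask_transmission = 0.01,
                         mask_phase = pi / 2)
  na_axis <- attr(f, "na_axis")
  rho <- sqrt(outer(na_axis^2, na_axis^2, `+`))
  inside <- rho <= cfg2$mask_cutoff_na
  g <- f
  g$ex[!inside] <- 0
  masked <- apply_bfp_mask(g, cfg2)
  expect_equal(sum(Mod(masked$ex)^2) / sum(Mod(g$ex)^2), 0.01,
               tolerance = 1e-12)
  # per-pixel oracle: direct complex multiplication
  expect_equal(masked$ex[inside], g$ex[inside] * 0.1 * 1i, tolerance = 1e-12)

  expect_error(apply_bfp_mask(gaussian_field(cfg), cfg), "BFP")
})
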