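# The worked operating point quoted throughout: printed rounded factors.
worked_params <- function(...) {
  snr_parameters(mu = 0.40, gamma = 1.58, a_bfp = 50e-6, ...)
}

test_that("derived factors: collection efficiency, BFP area, gamma", {
  p <- snr_parameters()
  d <- derived_factors(p)
  expect_equal(d$a_bfp * 1e6, 50, tolerance = 0.01)       # ~50 mm^2
  expect_equal(d$mu, asin(1.42 / 1.515) / pi, tolerance = 1e-12)
  # NA clamp: full hemisphere collection
  p2 <- snr_parameters(na = 1.6)
  expect_equal(derived_factors(p2)$mu, 0.5, tolerance = 1e-12)
})

test_that("gamma shows the interface enhancement the table quantifies", {
  expect_lt(abs(gamma_interface(1.42) - 1.58), 0.05)
  expect_lt(abs(gamma_interface(1.3) - 1.21), 0.05)
  expect_equal(gamma_interface(1.3, method = "table"), 1.21)
  # index matching removes the supercritical enhancement: the homogeneous
  # value reduces to the bulk in-plane-dipole collected fraction over mu
  th <- asin(1.2 / 1.515)
  frac_inplane <- (3 / 8) * ((1 - cos(th)) + (1 - cos(th)^3) / 3)
  g_hom <- gamma_interface(1.2, n_m = 1.515, n_g = 1.515)
  expect_equal(g_hom, frac_inplane / (th / pi), tolerance = 1e-6)
  expect_gt(gamma_interface(1.5), 1.5 * g_hom)
})

test_that("photon budgets scale as the closed forms dictate", {
  p <- worked_params()
  expect_equal(scattered_photons(worked_params(i_illu = 0)), 0)
  expect_equal(reflected_photons(worked_params(tau2 = 0)), 0)
  # N_sca quadratic in mass, N_ref linear in mask transmission
  expect_equal(scattered_photons(worked_params(m = 132)) /
                 scattered_photons(p), 4, tolerance = 1e-12)
  expect_equal(reflected_photons(worked_params(tau2 = 0.02)) /
                 reflected_photons(worked_params(tau2 = 0.002)), 10,
               tolerance = 1e-12)
})

test_that("SNR scalings: linear in m, sqrt in dose", {
  p <- worked_params()
  s <- shot_noise_snr(p)
  expect_equal(shot_noise_snr(worked_params(m = 132)) / s, 2,
               tolerance = 1e-12)
  expect_equal(shot_noise_snr(worked_params(dt = 0.4)) / s, 2,
               tolerance = 1e-12)
  expect_error(shot_noise_snr(worked_params(tau2 = 0)), "reflected")
})

test_that("detection limit and QCRLB invert the SNR chain exactly", {
  p <- worked_params()
  mq <- detection_limit_mass(p, 3)
  expect_equal(detection_limit_mass(p, 6), 2 * mq, tolerance = 1e-12)
  # round trip: SNR evaluated at m_q returns q
  expect_equal(shot_noise_snr(worked_params(m = mq)), 3, tolerance = 1e-10)
  # SNR-equivalent-mass identity for the resolution bound
  expect_equal(qcrlb_resolution(p), detection_limit_mass(p, 1 / sqrt(2)),
               tolerance = 1e-10)
  expect_equal(qcrlb_resolution(worked_params(i_illu = 4e9)),
               qcrlb_resolution(p) / 2, tolerance = 1e-12)
})

test_that("excess-noise SNR: shot-noise limit, quadrature, ceiling", {
  p <- worked_params()
  expect_equal(snr_with_excess(p), shot_noise_snr(p))
  p5 <- worked_params(sigma_exc = 5)
  expect_lt(snr_with_excess(p5), shot_noise_snr(p5))
  # unbounded flux saturates at m / sigma_exc
  expect_equal(snr_with_excess(worked_params(sigma_exc = 5, i_illu = 1e18)),
               66 / 5, tolerance = 1e-6)
})

test_that("the simplified kappa shorthand reproduces the full chain", {
  set.seed(42)
  for (i in 1:20) {
    p <- snr_parameters(i_illu = 10^runif(1, 7, 10), dt = 10^runif(1, -4, 0),
                        wavelength = runif(1, 4e-7, 6e-7),
                        m = runif(1, 10, 1000), tau2 = runif(1, 0.001, 0.1))
    kap <- kappa_constant(p)
    expect_equal(kap * p$m * sqrt(p$i_illu * p$dt / p$wavelength^5),
                 shot_noise_snr(p), tolerance = 1e-9)
    # kappa is dose- and mass-independent
    p2 <- p; p2$m <- p$m * 3; p2$i_illu <- p$i_illu * 7
    expect_equal(kappa_constant(p2), kap, tolerance = 1e-9)
  }
})

test_that("performance maps are monotone and respect the excess ceiling", {
  p <- worked_params(sigma_exc = 5)
  maps <- performance_maps(p, i_illu = 10^seq(8, 10, length.out = 6),
                           dt = 10^seq(-3, 0, length.out = 5))
  expect_true(all(diff(maps$snr) >= 0))          # increasing in intensity
  expect_true(all(apply(maps$snr, 1, diff) >= 0))  # and in exposure
  expect_true(all(maps$snr_exc <= 66 / 5 + 1e-9))
  expect_true(all(maps$snr_exc <= maps$snr + 1e-12))
  # shot-noise-limited regime reaches ~1 kDa resolution at ~1 MW/cm^2, <1 s
  p0 <- worked_params()
  m0 <- performance_maps(p0, i_illu = 1e10, dt = 0.5)
  expect_lt(m0$sigma_m[1, 1], 1)
})
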