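test_that("ratiometric contrast: identities and the small-signal closed form", {
  i_bkg <- matrix(2, 8, 8)
  expect_equal(ratiometric_contrast(i_bkg, i_bkg), matrix(0, 8, 8))
  expect_equal(ratiometric_contrast(1.01 * i_bkg, i_bkg),
               matrix(0.01, 8, 8), tolerance = 1e-12)
  expect_error(ratiometric_contrast(i_bkg, matrix(0, 8, 8)), "non-positive")
  expect_error(ratiometric_contrast(i_bkg, matrix(1, 4, 4)), "grid")
  # interferometric form 2(|s|/|r|)cos(phi) + (|s|/|r|)^2 for synthetic fields
  r <- 0.064; s <- 0.002
  for (phi in c(0, 0.7, pi / 2, 2.5)) {
    i_det <- Mod(r + s * exp(1i * phi))^2
    expect_equal(ratiometric_contrast(matrix(i_det, 1, 1), matrix(r^2, 1, 1))[1],
                 2 * (s / r) * cos(phi) + (s / r)^2, tolerance = 1e-12)
  }
})

test_that("zero scatterer yields a uniform reference image and zero contrast", {
  cfg <- optical_config(n_pix = 32)
  res <- image_point_source(cfg, scatterer_response(0))
  expect_equal(max(abs(res$contrast)), 0)
  expect_equal(stats::sd(res$i_det), 0, tolerance = 1e-15)
  expect_equal(res$i_bkg[1, 1],
               interface_reflectivity(cfg)^2 * cfg$mask_transmission,
               tolerance = 1e-12)
})

test_that("imaging is linear in the scattered field (small-signal regime)", {
  cfg <- optical_config(n_pix = 32, mask_transmission = 1, mask_phase = 0)
  r1 <- image_point_source(cfg, scatterer_response(2e4), n_az = 1)
  r2 <- image_point_source(cfg, scatterer_response(4e4), n_az = 1)
  i <- which.max(abs(r1$contrast))
  expect_equal(r2$contrast[i] / r1$contrast[i], 2, tolerance = 0.01)
})

test_that("contrast is invariant under a common rescaling of all lengths", {
  # wave-optics scale invariance: lambda, pixels and alpha ~ volume together
  cfg1 <- optical_config(n_pix = 32)
  cfg2 <- optical_config(n_pix = 32, wavelength = 2 * cfg1$wavelength,
                         d_px = 2 * cfg1$d_px)
  a <- 5e4
  c1 <- image_point_source(cfg1, scatterer_response(a), n_az = 1)$contrast
  c2 <- image_point_source(cfg2, scatterer_response(a * 8), n_az = 1)$contrast
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("a tenfold weaker mask boosts the contrast by sqrt(10)", {
  cfg1 <- optical_config(n_pix = 32, mask_transmission = 0.01)
  cfg01 <- optical_config(n_pix = 32, mask_transmission = 0.001)
  resp <- scatterer_response(4e4)
  p1 <- max(abs(image_point_source(cfg1, resp, n_az = 1)$contrast))
  p01 <- max(abs(image_point_source(cfg01, resp, n_az = 1)$contrast))
  expect_equal(p01 / p1, sqrt(10), tolerance = 0.05)
})

test_that("scatterer positions outside the field of view are rejected", {
  cfg <- optical_config(n_pix = 32)
  expect_error(image_point_source(cfg, scatterer_response(1e4),
                                  position = c(-1e-6, 0)), "outside")
})

test_that("circular illumination of a sphere is azimuthally even", {
  cfg <- optical_config(n_pix = 32)
  res <- image_point_source(cfg, scatterer_response(5e4), n_az = 4)
  c <- res$contrast
  # centre value matches any single linear polarization (isotropy)
  res1 <- image_point_source(cfg, scatterer_response(5e4), n_az = 1)
  i <- which.max(abs(c))
  expect_equal(c[i], res1$contrast[i], tolerance = 1e-6)
})
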