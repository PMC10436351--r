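test_that("landing schedules follow Poisson statistics and the seed contract", {
  sp <- bsa_species()
  expect_equal(nrow(schedule_landings(0, 1, 64, sp, seed = 1)), 0)
  e1 <- schedule_landings(50, 0.2, 64, sp, seed = 42)
  expect_identical(e1, schedule_landings(50, 0.2, 64, sp, seed = 42))
  expect_true(all(e1$x >= 0 & e1$x <= 64 & e1$y >= 0 & e1$y <= 64))
  expect_true(all(e1$frame >= 1 & e1$frame <= ceiling(0.2 / 5e-4)))
  # event-count mean over replicates ~ rate * duration within 3 sigma
  counts <- vapply(1:300, function(s)
    nrow(schedule_landings(40, 0.25, 64, sp, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 300))
})

test_that("species are drawn from the mixture weights", {
  sp <- bsa_species(2)
  sp$weight <- c(0.9, 0.1)
  ev <- schedule_landings(2000, 0.5, 64, sp, seed = 9)
  frac <- mean(ev$species == "bsa1")
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.09 / nrow(ev)))
})

test_that("noise-free movies reduce to the static background plus events", {
  cfg <- landing_config(32)
  surf <- flat_surface(32, cfg$d_px)
  st0 <- simulate_movie(acquisition_settings(n_frames = 4, seed = 1),
                        schedule_landings(0, 1e-3, 32, bsa_species(), seed = 1),
                        surf, cfg, shot_noise = FALSE)
  for (f in 1:4) expect_equal(st0$frames[, , f], st0$background,
                              tolerance = 1e-12)
})

test_that("shot noise is Poisson: per-pixel variance tracks the mean", {
  cfg <- landing_config(16)
  surf <- flat_surface(16, cfg$d_px)
  st <- simulate_movie(acquisition_settings(n_frames = 400,
                                            photons_per_px = 1e4, seed = 2),
                       schedule_landings(0, 1e-3, 16, bsa_species(), seed = 1),
                       surf, cfg)
  m <- apply(st$frames, c(1, 2), mean)
  v <- apply(st$frames, c(1, 2), stats::var)
  ratio <- v / m
  expect_lt(abs(mean(ratio) - 1), 0.05)
  expect_equal(mean(m), 1e4, tolerance = 0.01)
})

test_that("movies are bit-reproducible under their seed", {
  cfg <- landing_config(16)
  surf <- generate_height_map(16, cfg$d_px, seed = 3)
  ev <- schedule_landings(200, 5e-3, 16, bsa_species(), seed = 4)
  s <- acquisition_settings(n_frames = 10, seed = 5)
  expect_identical(simulate_movie(s, ev, surf, cfg)$frames,
                   simulate_movie(s, ev, surf, cfg)$frames)
})

test_that("events outside the grid are rejected", {
  cfg <- landing_config(16)
  ev <- schedule_landings(200, 5e-3, 16, bsa_species(), seed = 4)
  ev$x[1] <- 40
  expect_error(simulate_movie(acquisition_settings(n_frames = 4, seed = 1),
                              ev, flat_surface(16, cfg$d_px), cfg), "outside")
})

test_that("detector binning sums counts and conserves totals exactly", {
  set.seed(8)
  frames <- array(rpois(16 * 16 * 8, 100), dim = c(16, 16, 8))
  expect_identical(bin_detector(frames, 1, 1), frames)
  b <- bin_detector(frames, 2, 4)
  expect_equal(dim(b), c(8, 8, 2))
  expect_equal(sum(b), sum(frames))   # exact integer identity
  const <- array(100, dim = c(4, 4, 2))
  expect_true(all(bin_detector(const, 2, 1) == 400))
  expect_error(bin_detector(frames, 3, 1), "divide")
  expect_error(bin_detector(frames, 1, 3), "divide")
})

test_that("binned shot noise reaches the 1/sqrt(N) photon-budget scaling", {
  set.seed(9)
  lam <- 1e4
  frames <- array(rpois(8 * 8 * 100, lam), dim = c(8, 8, 100))
  b <- bin_detector(frames, 2, 25)   # 1e6 photoelectrons per binned sample
  rel <- stats::sd(b) / mean(b)
  expect_equal(rel, 1 / sqrt(lam * 4 * 25), tolerance = 0.15)
})

test_that("movie TIFF export round-trips counts exactly", {
  cfg <- landing_config(16)
  st <- simulate_movie(acquisition_settings(n_frames = 3,
                                            photons_per_px = 1e6, seed = 2),
                       schedule_landings(0, 1e-3, 16, bsa_species(), seed = 1),
                       flat_surface(16, cfg$d_px), cfg)
  tmp <- tempfile(fileext = ".tif")
  write_movie_tiff(st, tmp)
  back <- read_movie_tiff(tmp)
  expect_equal(array(as.numeric(back), dim = dim(back)),
               array(as.numeric(st$frames), dim = dim(st$frames)))
  expect_true(file.exists(sub("\\.tif$", "_settings.yaml", tmp)))
})
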