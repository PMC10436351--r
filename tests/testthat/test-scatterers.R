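test_that("sphere polarizability: index matching, volume scaling", {
  expect_equal(sphere_polarizability(sphere_scatterer(5e-9, 1.333, 1.333)), 0)
  a1 <- sphere_polarizability(sphere_scatterer(4e-9, 1.46))
  a2 <- sphere_polarizability(sphere_scatterer(8e-9, 1.46))
  expect_equal(a2 / a1, 8, tolerance = 1e-12)
  # direct evaluation of the documented Clausius-Mossotti expression
  a <- sphere_polarizability(sphere_scatterer(5.6e-9, 1.480))
  v <- 4 / 3 * pi * 5.6e-9^3
  expect_equal(a, 3 * v * (1.48^2 - 1.333^2) / (1.48^2 + 2 * 1.333^2) * 1e30,
               tolerance = 1e-12)
})

test_that("structure mass comes from the atoms present", {
  s <- atomic_structure(c("C", "C", "N", "O"),
                        rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)))
  expect_equal(s$mass_kda, (2 * 12.011 + 14.007 + 15.999) / 1000)
  expect_error(atomic_structure("XX", matrix(0, 1, 3)), "atomic mass")
})

test_that("single atom gives an isotropic tensor of its own polarizability", {
  s <- atomic_structure("C", matrix(0, 1, 3))
  t <- tensor_from_structure(s)
  a_c <- unname(atomic_polarizabilities()["C"])
  expect_equal(t$alpha, diag(3) * a_c, tolerance = 1e-12)
})

test_that("two-atom tensor matches a brute-force 6x6 coupled-dipole solve", {
  d <- 3.0   # angstrom, along z
  s <- atomic_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, d)))
  t <- tensor_from_structure(s)
  # independent oracle: solve the 6x6 system explicitly
  a <- unname(atomic_polarizabilities()["C"])
  tzz <- diag(c(-1, -1, 2)) / (4 * pi * d^3)   # (3 zz - I)/(4 pi d^3)
  m <- rbind(cbind(diag(3), -a * tzz), cbind(-a * tzz, diag(3)))
  expect_tensor <- matrix(0, 3, 3)
  for (dd in 1:3) {
    e <- rep(0, 3); e[dd] <- 1
    p <- solve(m, rep(a * e, 2))
    expect_tensor[, dd] <- p[1:3] + p[4:6]
  }
  expect_equal(t$alpha, (expect_tensor + t(expect_tensor)) / 2,
               tolerance = 1e-10)
  # qualitative structure: enhanced along the pair axis, reduced across
  expect_gt(t$alpha[3, 3], 2 * a)
  expect_lt(t$alpha[1, 1], 2 * a)
})

test_that("tensor reduces to the atomic sum when interactions vanish", {
  s <- random_cloud(12, seed = 4)
  t0 <- tensor_from_structure(s, interactions = FALSE)
  a_sum <- sum(atomic_polarizabilities()[s$elements])
  expect_equal(t0$alpha, diag(3) * a_sum, tolerance = 1e-12)
  # far-separated atoms converge to the same limit
  s2 <- atomic_structure(s$elements, s$xyz * 1e4)
  t2 <- tensor_from_structure(s2)
  expect_equal(t2$alpha, diag(3) * a_sum, tolerance = 1e-6)
})

test_that("atoms below the distance floor raise a conditioning error", {
  s <- atomic_structure(c("C", "C"), rbind(c(0, 0, 0), c(0.2, 0, 0)))
  expect_error(tensor_from_structure(s), "floor")
})

test_that("tensors are equivariant under rigid rotation of the structure", {
  s <- random_cloud(15, seed = 9)
  t <- tensor_from_structure(s)
  o <- local_seed_test(21, sample_orientation(1))
  r <- rotation_matrix(o)
  s_rot <- atomic_structure(s$elements, s$xyz %*% t(r))
  t_rot <- tensor_from_structure(s_rot)
  expect_equal(t_rot$alpha, r %*% t$alpha %*% t(r), tolerance = 1e-8)
  # and rotate_tensor implements exactly R alpha R^T
  expect_equal(rotate_tensor(t, o)$alpha, r %*% t$alpha %*% t(r),
               tolerance = 1e-12)
})

test_that("mean polarizability is rotation invariant and atom-monotone", {
  s <- random_cloud(10, seed = 2)
  t <- tensor_from_structure(s)
  for (i in 1:5) {
    o <- sample_orientation(1)
    expect_equal(mean_polarizability(rotate_tensor(t, o)),
                 mean_polarizability(t), tolerance = 1e-12)
  }
  # adding an atom never decreases <alpha> (randomized clouds)
  for (seed in 1:5) {
    s1 <- random_cloud(8, seed = seed)
    extra <- atomic_structure(c(s1$elements, "C"),
                              rbind(s1$xyz, max(s1$xyz) + c(3, 3, 3)))
    expect_gte(mean_polarizability(tensor_from_structure(extra)),
               mean_polarizability(tensor_from_structure(s1)))
  }
})

test_that("mean polarizability grows linearly with mass on uniform clouds", {
  # same composition and density, increasing size: <alpha> ~ mass
  sizes <- c(20, 40, 80, 160)
  res <- t(vapply(seq_along(sizes), function(i) {
    s <- random_cloud(sizes[i], seed = 30 + i)
    c(mass = s$mass_kda,
      alpha = mean_polarizability(tensor_from_structure(s)))
  }, numeric(2)))
  expect_gt(stats::cor(res[, "mass"], res[, "alpha"]), 0.99)
})

test_that("rotation matrices follow the z-y-x convention with det +1", {
  o <- orientation(0.3, -0.7, 1.2)
  r <- rotation_matrix(o)
  expect_equal(det(r), 1, tolerance = 1e-12)
  expect_equal(crossprod(r), diag(3), tolerance = 1e-12)
  # worked example: 90 deg about z swaps the first two diagonal entries
  t <- structure(list(alpha = diag(c(1, 2, 3)), frame = "structure",
                      source = "synthetic", mass_kda = 0),
                 class = "polarizability_tensor")
  t90 <- rotate_tensor(t, orientation(theta_z = pi / 2))
  expect_equal(t90$alpha, diag(c(2, 1, 3)), tolerance = 1e-12)
  # isotropic tensors are rotation invariant
  ti <- t; ti$alpha <- diag(3) * 5
  expect_equal(rotate_tensor(ti, orientation(0.4, 0.5, 0.6))$alpha, ti$alpha,
               tolerance = 1e-12)
})

test_that("orientation sampling is reproducible and uniform on SO(3)", {
  set.seed(11)
  o1 <- sample_orientation(2)
  set.seed(11)
  o2 <- sample_orientation(2)
  expect_identical(o1, o2)
  expect_false(identical(o1[[1]], o1[[2]]))

  set.seed(99)
  n <- 10000
  os <- sample_orientation(n)
  vs <- vapply(os, function(o) rotation_matrix(o) %*% c(1, 0, 0), numeric(3))
  # mean of R v over uniform rotations is 0, within 3 sigma MC error
  mc_sigma <- 1 / sqrt(3) / sqrt(n)
  expect_true(all(abs(rowMeans(vs)) < 3 * mc_sigma))
  # rotation-angle density follows (1 - cos theta)/pi
  angs <- vapply(os, function(o) {
    acos(pmin(1, pmax(-1, (sum(diag(rotation_matrix(o))) - 1) / 2)))
  }, numeric(1))
  cdf <- function(t) (t - sin(t)) / pi
  ks <- max(abs(seq_len(n) / n - cdf(sort(angs))))
  expect_lt(ks, 1.63 / sqrt(n) * 1.5)   # KS 1% level with slack
})

test_that("effective response projects the tensor onto the polarization", {
  t <- structure(list(alpha = diag(c(10, 4, 7)), frame = "lab",
                      source = "synthetic", mass_kda = 0),
                 class = "polarizability_tensor")
  expect_equal(effective_response(t, list(type = "linear", angle = 0))$alpha_a3, 10)
  expect_equal(effective_response(t, list(type = "linear", angle = pi / 2))$alpha_a3, 4)
  expect_equal(effective_response(t, "circular")$alpha_a3, 7)
  # isotropic tensor: identical under every polarization
  ti <- t; ti$alpha <- diag(3) * 5
  expect_equal(effective_response(ti, "circular")$alpha_a3,
               effective_response(ti, list(type = "linear", angle = 1.1))$alpha_a3)
  # scalar passthrough
  expect_equal(effective_response(1234)$alpha_a3, 1234)
})

test_that("PDB reading round-trips a synthetic structure", {
  # write a minimal PDB with two altlocs and read it back
  tmp <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.500   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BALA A   1       1.700   0.000   0.000  0.50  0.00           C",
    "ATOM      4  O   ALA A   1       0.000   1.500   0.000  1.00  0.00           O",
    "END")
  writeLines(lines, tmp)
  s <- read_structure_pdb(tmp)
  expect_equal(length(s$elements), 3)          # altloc B dropped
  expect_setequal(s$elements, c("N", "C", "O"))
  expect_equal(s$mass_kda, (14.007 + 12.011 + 15.999) / 1000)
})
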