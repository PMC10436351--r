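#' Rayleigh-sphere scatterer
#'
#' The simplest molecular model: a homogeneous dielectric sphere of refractive
#' index `n_p` embedded in buffer of index `n_m`. Valid in the Rayleigh
#' regime; a validity flag is set when the radius exceeds a tenth of typical
#' visible wavelengths (50 nm).
#'
#' @param radius Sphere radius (m).
#' @param n_p Particle refractive index.
#' @param n_m Medium refractive index.
#' @return An object of class `sphere_scatterer`.
#' @examples
#' sphere_scatterer(5.6e-9, 1.480)   # Hsp16.5 24-mer equivalent
#' @export
sphere_scatterer <- function(radius, n_p, n_m = 1.333) {
  stopifnot(radius > 0, n_p > 0, n_m > 0)
  structure(list(radius = radius, n_p = n_p, n_m = n_m,
                 rayleigh_valid = radius <= 50e-9),
            class = "sphere_scatterer")
}

#' Excess polarizability of a Rayleigh sphere
#'
#' Clausius-Mossotti form in the package's volume convention,
#' \deqn{\alpha = 3 V \frac{n_p^2 - n_m^2}{n_p^2 + 2 n_m^2}}
#' returned in cubic angstroms. In this convention the scattering
#' cross-section is \eqn{k^4 \alpha^2 / 6\pi} and the far-field scattering
#' amplitude is \eqn{k^2 \alpha E / 4\pi}; whether the wavenumber carries the
#' medium index is governed by the `k_convention` of [optical_config()].
#' The polarizability vanishes for an index-matched particle and scales with
#' the particle volume.
#'
#' @param sph A [sphere_scatterer()].
#' @return Scalar excess polarizability (A^3).
#' @export
sphere_polarizability <- function(sph) {
  stopifnot(inherits(sph, "sphere_scatterer"))
  v <- 4 / 3 * pi * sph$radius^3
  3 * v * (sph$n_p^2 - sph$n_m^2) / (sph$n_p^2 + 2 * sph$n_m^2) * 1e30
}

# ---------------------------------------------------------------------------
# atomic structures

atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, SE = 78.971, F = 18.998, CL = 35.45,
                   BR = 79.904, I = 126.904, FE = 55.845, ZN = 65.38,
                   MG = 24.305, CA = 40.078, "NA" = 22.990, K = 39.098,
                   MN = 54.938, CU = 63.546)

#' Atomic structure of a molecule
#'
#' Per-atom element symbols and coordinates, plus the structure mass computed
#' from the atoms actually present (the convention used throughout: a PDB
#' entry missing hydrogens or residues weighs what its listed atoms weigh,
#' not what the sequence would predict).
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix `n x 3` of coordinates (angstrom).
#' @param source Identifier (PDB ID or `"synthetic"`).
#' @param residue Optional integer vector of residue indices (enables
#'   per-residue coarse graining).
#' @return An object of class `atomic_structure` with a `mass_kda` field.
#' @export
atomic_structure <- function(elements, xyz, source = "synthetic",
                             residue = NULL) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1 || ncol(xyz) != 3) stop("xyz must be an n x 3 matrix")
  if (length(elements) != nrow(xyz)) stop("one element symbol per atom")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  elements <- toupper(trimws(elements))
  unknown <- setdiff(unique(elements), names(atomic_masses))
  if (length(unknown))
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  structure(list(elements = elements, xyz = xyz, source = source,
                 residue = residue,
                 mass_kda = sum(atomic_masses[elements]) / 1000),
            class = "atomic_structure")
}

#' Read an atomic structure from a PDB file
#'
#' Reads ATOM and HETATM records via \pkg{bio3d}, keeping the first model and
#' preferring alternate location `A`.
#'
#' @param path Path to a PDB file.
#' @param source Identifier stored with the structure; defaults to the file
#'   name.
#' @return An [atomic_structure()].
#' @export
read_structure_pdb <- function(path, source = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ]
  el <- toupper(trimws(at$elesy))
  miss <- is.na(el) | el == ""
  if (any(miss))  # fall back on the first letter of the atom name
    el[miss] <- toupper(substr(trimws(at$elety[miss]), 1, 1))
  atomic_structure(el, cbind(at$x, at$y, at$z), source = source,
                   residue = as.integer(factor(paste(at$chain, at$resno))))
}

#' Default atomic excess-polarizability table
#'
#' Per-element isotropic excess polarizabilities (A^3, package volume
#' convention) used as inputs of the coupled-dipole tensor model. Relative
#' magnitudes follow in-vacuo atomic polarizabilities (ionic values for
#' bound metals); the absolute scale is calibrated so that an average
#' protein elemental composition yields the mass-polarizability slope of
#' 724 A^3/kDa. The table ships as a config file
#' (`extdata/atomic_polarizabilities.csv`) so it can be swapped wholesale.
#'
#' @return Named numeric vector, A^3 per element.
#' @export
atomic_polarizabilities <- function() {
  path <- system.file("extdata", "atomic_polarizabilities.csv",
                      package = "iscatsim", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(tab$alpha_a3, toupper(tab$element))
}

#' Molecular polarizability tensor from an atomic structure
#'
#' Coupled-dipole model: every atom carries an isotropic atomic
#' polarizability; mutual dipole-dipole interactions over all pairwise
#' distances are solved self-consistently, and the molecular 3x3 tensor is
#' the total induced moment per unit applied field. The interaction is the
#' bare point-dipole tensor `(3 rr - I)/(4 pi r^3)` consistent with the
#' package volume convention; a hard distance floor guards conditioning.
#' When interactions are disabled (or all distances grow large) the tensor
#' reduces to the sum of atomic polarizabilities times the identity.
#'
#' @param structure An [atomic_structure()].
#' @param params Named polarizability table (A^3); default
#'   [atomic_polarizabilities()].
#' @param interactions Logical; `FALSE` gives the non-interacting sum.
#' @param distance_floor Minimum allowed pairwise distance (angstrom).
#' @param coarse_grain `"auto"` (coarse-grain above `cg_threshold` atoms when
#'   residue indices are available), `TRUE`, or `FALSE`. Coarse graining
#'   places one site per residue at the unweighted atom centroid carrying the
#'   summed atomic polarizability.
#' @param cg_threshold Atom count above which `"auto"` coarse-grains.
#' @return An object of class `polarizability_tensor`: fields `alpha`
#'   (symmetric 3x3 matrix, A^3), `frame` (`"structure"`), `source`,
#'   `mass_kda`.
#' @export
tensor_from_structure <- function(structure, params = atomic_polarizabilities(),
                                  interactions = TRUE, distance_floor = 0.8,
                                  coarse_grain = "auto", cg_threshold = 2000L) {
  stopifnot(inherits(structure, "atomic_structure"))
  el <- structure$elements
  unknown <- setdiff(unique(el), names(params))
  if (length(unknown))
    stop("no polarizability parameter for element(s): ",
         paste(unknown, collapse = ", "))
  a <- unname(params[el])
  xyz <- structure$xyz
  do_cg <- isTRUE(coarse_grain) ||
    (identical(coarse_grain, "auto") && nrow(xyz) > cg_threshold &&
       !is.null(structure$residue))
  if (do_cg) {
    if (is.null(structure$residue))
      stop("coarse graining needs residue indices")
    g <- structure$residue
    xyz <- do.call(rbind, lapply(split(seq_along(g), g), function(i)
      colMeans(xyz[i, , drop = FALSE])))
    a <- vapply(split(a, g), sum, numeric(1))
  }
  n <- nrow(xyz)
  if (!interactions || n == 1) {
    alpha <- diag(3) * sum(a)
  } else {
    dmin <- min(stats::dist(xyz))
    if (dmin < distance_floor)
      stop(sprintf("atoms closer than the %.2f A floor (min distance %.3f A);
interaction system would be ill-conditioned", distance_floor, dmin))
    m <- coupled_dipole_matrix(xyz, a)
    rhs <- matrix(0, 3 * n, 3)
    for (d in 1:3) rhs[seq(d, 3 * n, by = 3), d] <- a
    x <- solve(m, rhs)
    alpha <- matrix(0, 3, 3)
    for (d in 1:3)
      alpha[, d] <- c(sum(x[seq(1, 3 * n, 3), d]),
                      sum(x[seq(2, 3 * n, 3), d]),
                      sum(x[seq(3, 3 * n, 3), d]))
    asym <- max(abs(alpha - t(alpha))) / max(abs(alpha))
    if (asym > 1e-8)
      warning(sprintf("tensor asymmetry %.2e exceeds tolerance", asym))
    alpha <- (alpha + t(alpha)) / 2
  }
  structure(list(alpha = alpha, frame = "structure",
                 source = structure$source, mass_kda = structure$mass_kda),
            class = "polarizability_tensor")
}

# dense (I - diag(alpha) T) system matrix of the coupled-dipole solve
coupled_dipole_matrix <- function(xyz, a) {
  n <- nrow(xyz)
  m <- diag(3 * n)
  for (i in seq_len(n)) {
    ri <- xyz[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- ri - xyz[j, ]
      r2 <- sum(dr^2)
      r <- sqrt(r2)
      tij <- (3 * tcrossprod(dr) / r2 - diag(3)) / (4 * pi * r^3)
      m[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- -a[i] * tij
    }
  }
  m
}

#' Mean (scalar) polarizability of a tensor
#'
#' @param t A `polarizability_tensor`.
#' @return `trace(alpha)/3` in A^3; invariant under rotation.
#' @export
mean_polarizability <- function(t) {
  stopifnot(inherits(t, "polarizability_tensor"))
  sum(diag(t$alpha)) / 3
}

# ---------------------------------------------------------------------------
# orientations

#' Molecular orientation as intrinsic z-y-x Euler angles
#'
#' The rotation applied to a tensor is `R = Rz(theta_z) Ry(theta_y)
#' Rx(theta_x)`.
#'
#' @param theta_x,theta_y,theta_z Rotation angles (rad).
#' @return An object of class `orientation`.
#' @export
orientation <- function(theta_x = 0, theta_y = 0, theta_z = 0) {
  structure(list(theta_x = theta_x, theta_y = theta_y, theta_z = theta_z),
            class = "orientation")
}

#' Rotation matrix of an orientation
#'
#' @param o An [orientation()].
#' @return The orthonormal 3x3 matrix `Rz Ry Rx` (det +1).
#' @export
rotation_matrix <- function(o) {
  ca <- cos(o$theta_x); sa <- sin(o$theta_x)
  cb <- cos(o$theta_y); sb <- sin(o$theta_y)
  cc <- cos(o$theta_z); sc <- sin(o$theta_z)
  rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rotate a polarizability tensor
#'
#' `alpha_rot = R alpha R^T`; eigenvalues and trace are invariant.
#'
#' @param t A `polarizability_tensor`.
#' @param o An [orientation()].
#' @return The rotated tensor (frame labelled `"lab"`).
#' @export
rotate_tensor <- function(t, o) {
  stopifnot(inherits(t, "polarizability_tensor"), inherits(o, "orientation"))
  r <- rotation_matrix(o)
  out <- t
  out$alpha <- r %*% t$alpha %*% t(r)
  out$frame <- "lab"
  out
}

#' Draw orientations uniformly over the rotation group
#'
#' Uniform (Haar) sampling of SO(3) via unit quaternions, returned as the
#' package's z-y-x Euler angles. Uses R's global random number stream, so a
#' prior `set.seed()` makes the sequence reproducible.
#'
#' @param n Number of orientations.
#' @return A list of [orientation()] objects (an `orientation` itself for
#'   `n = 1`).
#' @export
sample_orientation <- function(n = 1) {
  draws <- lapply(seq_len(n), function(i) {
    u <- stats::runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    r <- quat_to_matrix(q)
    euler_zyx_from_matrix(r)
  })
  if (n == 1) draws[[1]] else draws
}

quat_to_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w)),
        c(2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w)),
        c(2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)))
}

euler_zyx_from_matrix <- function(r) {
  b <- asin(max(-1, min(1, -r[3, 1])))
  a <- atan2(r[3, 2], r[3, 3])
  c <- atan2(r[2, 1], r[1, 1])
  orientation(theta_x = a, theta_y = b, theta_z = c)
}

#' Effective scalar response of a scatterer under a polarization
#'
#' Projects a polarizability tensor (or passes a scalar through) onto the
#' illumination polarization: for linear polarization along the in-plane unit
#' vector at `angle`, the driven response is `e^T alpha e`; for circular
#' polarization it is the azimuthal average of the in-plane linear responses,
#' `(alpha_xx + alpha_yy)/2`. An isotropic tensor responds identically under
#' every polarization and orientation.
#'
#' @param x A `polarizability_tensor` (already rotated into the lab frame) or
#'   a scalar polarizability (A^3).
#' @param polarization `"circular"` or `list(type = "linear", angle = <rad>)`.
#' @param height Scatterer height passed through to [scatterer_response()].
#' @return A [scatterer_response()].
#' @export
effective_response <- function(x, polarization = "circular", height = 0) {
  if (is.numeric(x) && length(x) == 1)
    return(scatterer_response(x, height))
  stopifnot(inherits(x, "polarizability_tensor"))
  if (!is.list(polarization))
    polarization <- list(type = match.arg(polarization, c("circular", "linear")),
                         angle = 0)
  a <- x$alpha
  s <- if (polarization$type == "circular") (a[1, 1] + a[2, 2]) / 2
  else {
    e <- c(cos(polarization$angle), sin(polarization$angle), 0)
    drop(t(e) %*% a %*% e)
  }
  scatterer_response(Re(s), height)
}

#' Export a polarizability tensor as JSON
#'
#' @param t A `polarizability_tensor`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tensor_json <- function(t, path) {
  jsonlite::write_json(list(alpha_a3 = t$alpha, frame = t$frame,
                            source = t$source, mass_kda = t$mass_kda),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
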