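# Shared fixtures, all generated in code.

# Fig-1 style configuration: fine pixels, zero-phase 1% mask
fig1_config <- function(...) {
  optical_config(d_px = 57e-9, n_pix = 70L, mask_phase = 0,
                 mask_transmission = 0.01, ...)
}

# landing-assay configuration: 0.1% mask with pi/2 phase
landing_config <- function(n_pix = 64L, ...) {
  optical_config(n_pix = n_pix, d_px = 70e-9, mask_transmission = 0.001,
                 mask_phase = pi / 2, ...)
}

hsp_response <- function() {
  scatterer_response(sphere_polarizability(sphere_scatterer(5.6e-9, 1.480)))
}

bsa_species <- function(n_oligomers = 1L) {
  # BSA oligomers as spheres of equal density: radius scales with n^(1/3)
  data.frame(label = paste0("bsa", seq_len(n_oligomers)),
             mass_kda = 66 * seq_len(n_oligomers),
             radius = 3.8e-9 * seq_len(n_oligomers)^(1 / 3),
             n_p = 1.46)
}

# gaussian-spot field map; band_limit (fraction of the medium wavenumber)
# removes evanescent and grid-truncation tails so that propagation round
# trips are exact
gaussian_field <- function(config, waist = 6 * config$d_px,
                           band_limit = 0.85) {
  n <- config$n_pix
  x <- (seq_len(n) - n / 2) * config$d_px
  g <- exp(-outer(x^2, x^2, `+`) / waist^2) + 0i
  if (!is.null(band_limit)) {
    km <- 2 * pi * config$n_m / config$wavelength
    kr <- iscatsim:::k_grids(n, config$d_px)$kr
    sp <- stats::fft(g)
    sp[kr > band_limit * km] <- 0
    g <- stats::fft(sp, inverse = TRUE) / length(sp)
  }
  field_map(g, config = config)
}

# random small atom cloud with typical protein elements; atoms sit on a
# jittered 3-angstrom grid, which guarantees pairwise separation
random_cloud <- function(n_atoms, seed, spread = NULL) {
  local_seed_test(seed, {
    el <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                 prob = c(0.6, 0.16, 0.2, 0.04))
    side <- ceiling(n_atoms^(1 / 3)) + 1
    cells <- sample(side^3, n_atoms)
    ijk <- cbind(cells %% side, (cells %/% side) %% side, cells %/% side^2)
    xyz <- ijk * 3 + matrix(stats::runif(3 * n_atoms, -0.5, 0.5), ncol = 3)
    atomic_structure(el, xyz)
  })
}

# evaluate a psf_model patch (internal helper surfaced for the tests)
psf_eval_window_for_tests <- function(model, dx, dy, half) {
  iscatsim:::psf_eval_window(model, dx, dy, half)
}

local_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
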