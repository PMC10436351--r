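#' Acquisition settings of a simulated landing-assay movie
#'
#' @param n_frames Number of raw camera frames.
#' @param exposure Exposure time per frame (s). Default 500 us.
#' @param photons_per_px Expected photons per pixel per frame on the flat
#'   background (default 1e6, matching 1e7 photoelectrons per pixel per
#'   ratiometric half-stack at `n_avg = 10`).
#' @param binning Spatial binning factor applied by [bin_detector()].
#' @param n_avg Ratiometric averaging window (frames per half-stack).
#' @param seed Integer seed of the movie's single RNG stream.
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(n_frames = 400L, exposure = 5e-4,
                                 photons_per_px = 1e6, binning = 1L,
                                 n_avg = 10L, seed = 1L) {
  stopifnot(n_frames >= 1, exposure > 0, photons_per_px > 0,
            binning >= 1, n_avg >= 1, is.finite(photons_per_px))
  structure(list(n_frames = as.integer(n_frames), exposure = exposure,
                 photons_per_px = photons_per_px, binning = as.integer(binning),
                 n_avg = as.integer(n_avg), seed = as.integer(seed)),
            class = "acquisition_settings")
}

#' Poisson landing schedule
#'
#' Draws nonspecific surface-binding events as a homogeneous Poisson process
#' in time, with uniform landing positions across the field of view, species
#' drawn from the mixture weights, and (for tensor species) orientations from
#' [sample_orientation()].
#'
#' @param rate Expected events per second.
#' @param duration Movie duration (s).
#' @param fov_px Field-of-view size (pixels, square).
#' @param species A data.frame with one row per species: columns `label`,
#'   `mass_kda`, and either `radius`/`n_p` (sphere model) or `alpha_a3`
#'   (precomputed effective polarizability); optional `weight`.
#' @param exposure Frame exposure (s), to convert times to frame indices.
#' @param seed Integer seed.
#' @return A data.frame of landing events: `time`, `frame`, `x`, `y`
#'   (subpixel, pixels from the corner), `species`, `mass_kda`, and Euler
#'   angles `theta_x`, `theta_y`, `theta_z`.
#' @export
schedule_landings <- function(rate, duration, fov_px, species,
                              exposure = 5e-4, seed = 1L) {
  stopifnot(rate >= 0, duration > 0)
  local_seed(seed, {
    n <- stats::rpois(1, rate * duration)
    if (n == 0) {
      return(data.frame(time = numeric(0), frame = integer(0),
                        x = numeric(0), y = numeric(0),
                        species = character(0), mass_kda = numeric(0),
                        theta_x = numeric(0), theta_y = numeric(0),
                        theta_z = numeric(0)))
    }
    w <- if ("weight" %in% names(species)) species$weight else
      rep(1, nrow(species))
    idx <- sample.int(nrow(species), n, replace = TRUE, prob = w)
    os <- sample_orientation(n)
    if (n == 1) os <- list(os)
    ev <- data.frame(
      time = sort(stats::runif(n, 0, duration)),
      x = stats::runif(n, 0, fov_px), y = stats::runif(n, 0, fov_px),
      species = species$label[idx], mass_kda = species$mass_kda[idx],
      theta_x = vapply(os, `[[`, numeric(1), "theta_x"),
      theta_y = vapply(os, `[[`, numeric(1), "theta_y"),
      theta_z = vapply(os, `[[`, numeric(1), "theta_z"))
    ev$frame <- pmin(ceiling(ev$time / exposure), ceiling(duration / exposure))
    ev$radius <- if ("radius" %in% names(species)) species$radius[idx] else NA
    ev$n_p <- if ("n_p" %in% names(species)) species$n_p[idx] else NA
    ev$alpha_a3 <- if ("alpha_a3" %in% names(species))
      species$alpha_a3[idx] else NA
    ev
  })
}

#' Simulate a landing-assay movie
#'
#' Renders the photon-count frame stack of a landing assay: the static
#' speckle background of the rough cover glass, plus, from each event's
#' landing frame onward, the interferometric point-spread function of that
#' molecule at its subpixel position (events persist; a landed molecule
#' becomes part of the background). Frame intensities are scaled so the mean
#' background expectation equals `settings$photons_per_px`, and independent
#' Poisson shot noise is applied per pixel per frame (disable with
#' `shot_noise = FALSE` for calibration-grade movies).
#'
#' @param settings An [acquisition_settings()].
#' @param events A landing schedule from [schedule_landings()].
#' @param surface A [rough_surface()] (or [flat_surface()]).
#' @param config An [optical_config()]; its grid must match the surface.
#' @param shot_noise Logical, apply Poisson noise (default TRUE).
#' @param patch_radius Pixels kept around each event PSF (default 12; beyond
#'   this the model contribution is below shot noise).
#' @return An object of class `frame_stack`: integer (or numeric, if
#'   noise-free) array `frames` of dim `c(n_pix, n_pix, n_frames)`, the
#'   settings, config, ground-truth event table and surface.
#' @export
simulate_movie <- function(settings, events, surface, config,
                           shot_noise = TRUE, patch_radius = 12L) {
  n <- config$n_pix
  if (nrow(surface$height) != n) stop("surface grid does not match config")
  if (nrow(events) > 0 &&
      any(events$x < 0 | events$x > n | events$y < 0 | events$y > n))
    stop("landing event outside the grid")
  grid <- imaging_grid(config)
  bg <- reference_field(config, grid, roughness = surface)
  e_bg <- bg$field
  scale <- settings$photons_per_px / mean(Mod(e_bg)^2)

  # per-event complex field patches at their subpixel positions
  mv <- mask_values(config, grid)
  beta <- 0  # single linear polarization; see vignette on sphere isotropy
  patches <- vector("list", nrow(events))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      resp <- event_response(events[i, ], config)
      sp <- scattered_spectrum(config, resp, grid, beta = beta)
      x0 <- events$x[i] * config$d_px
      y0 <- events$y[i] * config$d_px
      ex <- spectrum_to_image(sp$ex * mv, grid, config, x0, y0)
      patches[[i]] <- crop_patch(ex, events$x[i], events$y[i], patch_radius)
    }
  }

  # noise-free intensity changes only at landing frames: build per-segment
  # expectation images, then draw counts frame by frame
  frames <- array(if (shot_noise) 0L else 0, dim = c(n, n, settings$n_frames))
  e_tot <- e_bg
  land_frames <- if (nrow(events)) events$frame else integer(0)
  lambda <- Mod(e_tot)^2 * scale
  local_seed(settings$seed, {
    for (f in seq_len(settings$n_frames)) {
      landed_now <- which(land_frames == f)
      if (length(landed_now)) {
        for (i in landed_now) e_tot <- add_patch(e_tot, patches[[i]])
        lambda <- Mod(e_tot)^2 * scale
      }
      frames[, , f] <- if (shot_noise)
        matrix(stats::rpois(n * n, lambda), n, n) else lambda
    }
  })
  structure(list(frames = frames, settings = settings, config = config,
                 events = events, surface = surface,
                 background = Mod(e_bg)^2 * scale,
                 flat_level = bg$flat_level * scale),
            class = "frame_stack")
}

# build the scatterer_response for one scheduled event
event_response <- function(ev, config) {
  if (!is.na(ev$alpha_a3)) return(scatterer_response(ev$alpha_a3))
  sph <- sphere_scatterer(ev$radius, ev$n_p, config$n_m)
  scatterer_response(sphere_polarizability(sph))
}

crop_patch <- function(img, x_px, y_px, radius) {
  n <- nrow(img)
  ix <- floor(x_px) + 1
  iy <- floor(y_px) + 1
  xs <- max(1, ix - radius):min(n, ix + radius)
  ys <- max(1, iy - radius):min(n, iy + radius)
  list(xs = xs, ys = ys, values = img[xs, ys])
}

add_patch <- function(field, patch) {
  field[patch$xs, patch$ys] <- field[patch$xs, patch$ys] + patch$values
  field
}

#' Detector binning of a frame stack
#'
#' Sums photon counts over `spatial x spatial` pixel blocks and over
#' `temporal` consecutive frames. Totals are conserved exactly (integer
#' identity); factors must divide the grid and frame count.
#'
#' @param stack A `frame_stack` (or plain 3-d array of counts).
#' @param spatial Spatial binning factor.
#' @param temporal Temporal summing factor.
#' @return The binned stack in the same form as the input.
#' @export
bin_detector <- function(stack, spatial = 1L, temporal = 1L) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  d <- dim(frames)
  if (d[1] %% spatial != 0 || d[2] %% spatial != 0)
    stop("invalid config: spatial factor does not divide the grid")
  if (d[3] %% temporal != 0)
    stop("invalid config: temporal factor does not divide the frame count")
  if (spatial > 1) {
    n1 <- d[1] %/% spatial
    n2 <- d[2] %/% spatial
    dim(frames) <- c(spatial, n1, spatial, n2, d[3])
    frames <- colSums(aperm(frames, c(1, 3, 2, 4, 5)), dims = 2)
    d <- dim(frames)
  }
  if (temporal > 1) {
    nt <- d[3] %/% temporal
    dim(frames) <- c(d[1] * d[2], temporal, nt)
    frames <- aperm(frames, c(2, 1, 3))
    frames <- colSums(frames)
    dim(frames) <- c(d[1], d[2], nt)
  }
  if (inherits(stack, "frame_stack")) {
    out <- stack
    out$frames <- frames
    out$settings$binning <- stack$settings$binning * spatial
    out
  } else frames
}

#' Write a movie as a multi-page TIFF
#'
#' Counts are stored as 32-bit samples (scaled by `2^32 - 1` internally by
#' the TIFF writer); they round-trip exactly for counts below 2^31 when read
#' back with `tiff::readTIFF(..., as.is = TRUE)`. A YAML sidecar records the
#' acquisition settings and the ground-truth events go to a CSV next to it.
#'
#' @param stack A `frame_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(f)
    stack$frames[, , f] / (2^32 - 1))
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  meta <- sub("\\.tiff?$", "", path)
  yaml::write_yaml(list(n_frames = stack$settings$n_frames,
                        exposure_s = stack$settings$exposure,
                        photons_per_px = stack$settings$photons_per_px,
                        n_avg = stack$settings$n_avg,
                        seed = stack$settings$seed,
                        count_scale = 2^32 - 1),
                   paste0(meta, "_settings.yaml"))
  if (nrow(stack$events) > 0)
    utils::write.csv(stack$events, paste0(meta, "_events.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path.
#' @return Integer array of counts, dim `c(nx, ny, n_frames)`.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]]
  arr
}
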