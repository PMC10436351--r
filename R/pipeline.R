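#' Ratiometric transform of a raw frame stack
#'
#' For each sliding index i, averages the `n_avg` raw frames starting at i
#' into a first half-stack and the next `n_avg` frames into a second, and
#' outputs their relative difference `(I2 - I1)/I1`. A static background
#' cancels exactly in the noise-free case; a landing event fades in and out
#' of consecutive ratiometric frames as it crosses the window boundary, with
#' full amplitude when the landing falls exactly between the half-stacks.
#'
#' @param stack A `frame_stack` from [simulate_movie()] or a numeric 3-d
#'   array of counts.
#' @param n_avg Frames per half-stack; taken from the stack's settings when
#'   omitted.
#' @return An object of class `ratio_stack`: array `ratio` of dim
#'   `c(nx, ny, n_raw - 2 n_avg + 1)`, plus `n_avg` and the provenance link.
#' @export
ratiometric_stack <- function(stack, n_avg = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (is.null(n_avg)) {
    n_avg <- if (inherits(stack, "frame_stack")) stack$settings$n_avg else
      stop("n_avg is required for a bare array")
  }
  d <- dim(frames)
  n_t <- d[3]
  if (n_t < 2 * n_avg) stop("too few frames for the requested window")
  n_out <- n_t - 2 * n_avg + 1
  # cumulative sum along time for O(1) windowed means
  flat <- matrix(as.numeric(frames), d[1] * d[2], n_t)
  cs <- cbind(0, t(apply(flat, 1, cumsum)))
  win <- function(i0) (cs[, i0 + n_avg] - cs[, i0]) / n_avg   # frames i0..i0+n_avg-1
  ratio <- array(0, dim = c(d[1], d[2], n_out))
  for (i in seq_len(n_out)) {
    m1 <- win(i)
    m2 <- win(i + n_avg)
    ratio[, , i] <- matrix((m2 - m1) / m1, d[1], d[2])
  }
  src <- if (inherits(stack, "frame_stack")) stack else NULL
  # Poisson propagation: sd of (m2 - m1)/m1 for half-stacks of n_avg frames
  # with per-pixel expectation N_bg
  sigma <- if (!is.null(src) && !is.null(src$background))
    sqrt(2 / (n_avg * pmax(src$background, 1))) else NULL
  structure(list(ratio = ratio, n_avg = n_avg, sigma = sigma, source = src),
            class = "ratio_stack")
}

#' Detect landing events in a ratiometric stack
#'
#' Candidates must stand `min_snr` sigma above the per-pixel ratiometric
#' noise (propagated from the source movie's background photon counts when
#' available -- on a speckled background darker reference pixels are noisier
#' -- otherwise the stack's global temporal scatter), be local maxima of their
#' neighbourhood, and their surrounding patch must meet a minimum radial
#' symmetry (correlation of the patch with its angular average). Secondary
#' maxima on the Airy rings of a stronger candidate are suppressed within
#' `nms_radius`. Candidates at the same position in nearby frames are merged
#' into one event, reported at its maximal-|R| frame; an event must persist
#' for at least `min_frames` ratiometric frames, which suppresses
#' single-frame shot-noise outliers.
#'
#' @param stack A `ratio_stack`.
#' @param min_snr Detection threshold in units of the per-pixel noise
#'   (default 5).
#' @param min_amplitude Optional absolute floor on `|R|` (default 0).
#' @param min_radial_symmetry Radial-symmetry score threshold in `[0, 1]`
#'   (default 0.4).
#' @param min_frames Minimum frame persistence (default 2).
#' @param patch_half Patch half-width for the symmetry score (default 3,
#'   i.e. 7x7).
#' @param nms_radius Minimum separation (px) between candidates within one
#'   frame (default 5).
#' @return A data.frame of candidates: `frame`, `x`, `y` (pixel indices),
#'   `amplitude` (signed R at the peak), `symmetry`.
#' @export
detect_events <- function(stack, min_snr = 5, min_amplitude = 0,
                          min_radial_symmetry = 0.4, min_frames = 2L,
                          patch_half = 3L, nms_radius = 5) {
  stopifnot(inherits(stack, "ratio_stack"))
  r <- stack$ratio
  d <- dim(r)
  stopifnot(min_snr >= 0, min_amplitude >= 0, min_radial_symmetry >= 0)
  # per-pixel noise: the Poisson-propagated map when the stack knows its
  # source movie, otherwise the global temporal MAD of the stack
  if (!is.null(stack$sigma)) {
    sig <- stack$sigma
  } else {
    sig <- matrix(stats::mad(r), dim(r)[1], dim(r)[2])
    if (all(sig == 0)) sig[] <- 1  # noise-free: amplitude-only criterion
  }
  cand <- list()
  for (f in seq_len(d[3])) {
    fr <- r[, , f]
    a <- abs(fr)
    s <- a / sig
    peak <- which(s >= min_snr & a >= min_amplitude & s == max3x3(s),
                  arr.ind = TRUE)
    if (nrow(peak) == 0) next
    peak <- nonmax_suppress(peak, a[peak], nms_radius)
    keep <- logical(nrow(peak))
    sym <- numeric(nrow(peak))
    for (j in seq_len(nrow(peak))) {
      p <- extract_patch(fr, peak[j, 1], peak[j, 2], patch_half)
      sym[j] <- radial_symmetry(p)
      keep[j] <- is.finite(sym[j]) && sym[j] >= min_radial_symmetry
    }
    if (any(keep))
      cand[[length(cand) + 1]] <- data.frame(
        frame = f, x = peak[keep, 1], y = peak[keep, 2],
        amplitude = fr[peak[keep, , drop = FALSE]], symmetry = sym[keep])
  }
  if (!length(cand))
    return(data.frame(frame = integer(0), x = integer(0), y = integer(0),
                      amplitude = numeric(0), symmetry = numeric(0)))
  cand <- do.call(rbind, cand)
  dedup_candidates(cand, min_frames, frame_window = 2L * stack$n_avg + 2L)
}

# keep only the strongest candidate within nms_radius in one frame
nonmax_suppress <- function(peak, amp, radius) {
  o <- order(-amp)
  peak <- peak[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(peak))
  for (i in seq_len(nrow(peak))) {
    if (!keep[i]) next
    if (i < nrow(peak)) {
      later <- (i + 1):nrow(peak)
      d2 <- (peak[later, 1] - peak[i, 1])^2 + (peak[later, 2] - peak[i, 2])^2
      keep[later][d2 <= radius^2] <- FALSE
    }
  }
  peak[keep, , drop = FALSE]
}

max3x3 <- function(a) {
  n1 <- nrow(a); n2 <- ncol(a)
  out <- a
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- a[pmin(pmax(seq_len(n1) + dx, 1), n1),
            pmin(pmax(seq_len(n2) + dy, 1), n2)]
    out <- pmax(out, sh)
  }
  out
}

extract_patch <- function(img, i, j, half) {
  n1 <- nrow(img); n2 <- ncol(img)
  xs <- pmin(pmax((i - half):(i + half), 1), n1)
  ys <- pmin(pmax((j - half):(j + half), 1), n2)
  img[xs, ys]
}

# correlation of a patch with its angular average around the centre
radial_symmetry <- function(p) {
  h <- (nrow(p) - 1) / 2
  xs <- matrix(-h:h, nrow(p), ncol(p))
  rr <- round(sqrt(xs^2 + t(xs)^2))
  avg <- stats::ave(as.numeric(p), as.numeric(rr))
  v <- stats::sd(p)
  if (!is.finite(v) || v == 0) return(0)
  suppressWarnings(stats::cor(as.numeric(p), avg))
}

# Merge candidates that belong to one landing: greedy clustering seeded at
# the strongest candidates; a candidate joins a cluster when it sits within
# 2.5 px of the cluster peak and within the ratiometric support window
# (2 n_avg + 2 frames) of it.
dedup_candidates <- function(cand, min_frames, frame_window = 22L) {
  o <- order(-abs(cand$amplitude))
  cand <- cand[o, ]
  gid <- rep(NA_integer_, nrow(cand))
  px <- numeric(0); py <- numeric(0); pf <- integer(0)   # cluster peaks
  for (i in seq_len(nrow(cand))) {
    hit <- which(abs(px - cand$x[i]) <= 2.5 & abs(py - cand$y[i]) <= 2.5 &
                   abs(pf - cand$frame[i]) <= frame_window)
    if (length(hit)) {
      gid[i] <- hit[1]
    } else {
      px <- c(px, cand$x[i]); py <- c(py, cand$y[i])
      pf <- c(pf, cand$frame[i])
      gid[i] <- length(px)
    }
  }
  out <- do.call(rbind, lapply(split(cand, gid), function(g) {
    if (length(unique(g$frame)) < min_frames) return(NULL)
    g[which.max(abs(g$amplitude)), ]
  }))
  if (is.null(out))
    return(data.frame(frame = integer(0), x = integer(0), y = integer(0),
                      amplitude = numeric(0), symmetry = numeric(0)))
  rownames(out) <- NULL
  out$group <- NULL
  out
}

#' Theoretical ratiometric PSF model
#'
#' Renders the in-focus ratiometric contrast pattern of a unit point
#' scatterer with the movie's optical configuration, oversampled for
#' subpixel interpolation, normalized to unit peak. Used as the fit model of
#' [fit_event_contrast()].
#'
#' @param config An [optical_config()].
#' @param oversample Oversampling factor (default 8).
#' @param half Patch half-width in detector pixels (default 6).
#' @return An object of class `psf_model`: oversampled matrix `values`,
#'   factor `os`, half-width `half`.
#' @export
psf_model_theoretical <- function(config, oversample = 8L, half = 6L) {
  cfg <- config
  cfg$n_pix <- as.integer(2 * half * oversample + 1)
  cfg$d_px <- config$d_px / oversample
  # the patch field of view is sub-micron, so a modest pupil sampling is
  # enough and keeps the zero-padded transform small
  res <- image_point_source(cfg, scatterer_response(1e5), z_sample = 0,
                            n_az = 2L, n_pupil = 64L)
  m <- res$contrast / res$contrast[which.max(abs(res$contrast))]
  structure(list(values = m, os = oversample, half = half), class = "psf_model")
}

# evaluate a psf_model at detector-pixel offsets (dx, dy) from its centre,
# on the (2 half + 1)^2 patch grid, by bilinear interpolation
psf_eval <- function(model, dx, dy) {
  os <- model$os
  half <- model$half
  n <- nrow(model$values)
  ctr <- (n + 1) / 2
  px <- (-half:half)
  xi <- ctr + (matrix(px, length(px), length(px)) - dx) * os
  yi <- ctr + (t(matrix(px, length(px), length(px))) - dy) * os
  bilinear(model$values, xi, yi)
}

bilinear <- function(m, xi, yi) {
  n1 <- nrow(m); n2 <- ncol(m)
  x0 <- pmin(pmax(floor(xi), 1), n1 - 1)
  y0 <- pmin(pmax(floor(yi), 1), n2 - 1)
  fx <- pmin(pmax(xi - x0, 0), 1)
  fy <- pmin(pmax(yi - y0, 0), 1)
  v <- m[cbind(as.numeric(x0), as.numeric(y0))] * (1 - fx) * (1 - fy) +
    m[cbind(as.numeric(x0 + 1), as.numeric(y0))] * fx * (1 - fy) +
    m[cbind(as.numeric(x0), as.numeric(y0 + 1))] * (1 - fx) * fy +
    m[cbind(as.numeric(x0 + 1), as.numeric(y0 + 1))] * fx * fy
  matrix(v, nrow(xi), ncol(xi))
}

#' Fit the PSF model to a detected event patch
#'
#' Least-squares fit of amplitude and subpixel position of the (theoretical
#' or experimental) PSF model to a ratiometric patch centred on the
#' candidate pixel. The fitted amplitude is the event's ratiometric
#' contrast.
#'
#' @param patch Square ratiometric patch (odd side), centred on the
#'   candidate.
#' @param psf_model A `psf_model` from [psf_model_theoretical()] or
#'   [build_experimental_psf()].
#' @return An object of class `detected_event`: `contrast`, `dx`, `dy`
#'   (subpixel offsets), `residual` (RMS of the fit residuals), and
#'   `converged`.
#' @export
fit_event_contrast <- function(patch, psf_model) {
  half <- (nrow(patch) - 1) / 2
  if (half > psf_model$half)
    stop("patch larger than the PSF model support")
  model_half <- half
  obj <- function(par) {
    m <- psf_eval_window(psf_model, par[2], par[3], model_half)
    sum((patch - par[1] * m)^2)
  }
  a0 <- patch[half + 1, half + 1]
  fit <- stats::optim(c(a0, 0, 0), obj, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  m <- psf_eval_window(psf_model, fit$par[2], fit$par[3], model_half)
  # refit amplitude exactly given the position (linear parameter)
  a <- sum(patch * m) / sum(m^2)
  structure(list(contrast = a, dx = fit$par[2], dy = fit$par[3],
                 residual = sqrt(mean((patch - a * m)^2)),
                 converged = fit$convergence == 0),
            class = "detected_event")
}

psf_eval_window <- function(model, dx, dy, half) {
  full <- psf_eval(model, dx, dy)
  ctr <- model$half + 1
  full[(ctr - half):(ctr + half), (ctr - half):(ctr + half)]
}

#' Experimental PSF model from detected event patches
#'
#' Aligns the cropped patches of detected landing events to a common centre
#' by interpolated subpixel shifts, rejects outliers whose Pearson
#' correlation with the running mean falls below `cor_threshold`, and
#' averages the rest into an interpolable model (unit peak).
#'
#' @param patches List of equally sized square patches (>= 10 recommended).
#' @param psf_model Initial model used to find each patch's subpixel centre
#'   (defaults to a centred fit against the patch mean).
#' @param cor_threshold Pearson correlation below which a patch is dropped.
#' @param oversample Oversampling of the returned model grid.
#' @return A `psf_model`.
#' @export
build_experimental_psf <- function(patches, psf_model = NULL,
                                   cor_threshold = 0.7, oversample = 8L) {
  stopifnot(length(patches) >= 2)
  half <- (nrow(patches[[1]]) - 1) / 2
  ref <- Reduce(`+`, patches) / length(patches)
  cors <- vapply(patches, function(p) stats::cor(as.numeric(p),
                                                 as.numeric(ref)), numeric(1))
  keep <- which(is.finite(cors) & cors >= cor_threshold)
  if (!length(keep)) stop("all patches rejected as outliers")
  aligned <- 0
  for (i in keep) {
    p <- patches[[i]]
    ctr <- patch_centroid(p)
    aligned <- aligned + shift_patch(p, -ctr[1], -ctr[2])
  }
  aligned <- aligned / length(keep)
  # oversample by spline interpolation onto the model grid
  vals <- spline_oversample(aligned, oversample)
  vals <- vals / vals[which.max(abs(vals))]
  structure(list(values = vals, os = oversample, half = half),
            class = "psf_model")
}

patch_centroid <- function(p) {
  h <- (nrow(p) - 1) / 2
  w <- abs(p)^2
  xs <- matrix(-h:h, nrow(p), ncol(p))
  c(sum(xs * w), sum(t(xs) * w)) / sum(w)
}

shift_patch <- function(p, dx, dy) {
  n <- nrow(p)
  xi <- matrix(seq_len(n), n, n) - dx
  yi <- t(matrix(seq_len(n), n, n)) - dy
  bilinear(p, xi, yi)
}

spline_oversample <- function(m, os) {
  n <- nrow(m)
  xf <- seq(1, n, length.out = (n - 1) * os + 1)
  tmp <- apply(m, 2, function(col) stats::spline(seq_len(n), col,
                                                 xout = xf)$y)
  t(apply(t(tmp), 2, function(row) stats::spline(seq_len(n), row,
                                                 xout = xf)$y))
}

#' Local reflectivity correction of a ratiometric stack
#'
#' Pixel-wise variant of the local reflectivity correction: every ratiometric
#' frame is multiplied by `sqrt(I_bkg(x) / I_flat)`. Because the
#' roughness-induced speckle modulates mainly the local reference amplitude
#' (its phase, to first order, follows the mask-shifted reference), this
#' cancels the `1/|r_local|` scaling of the contrast at every pixel and at
#' the same time undoes the speckle distortion of the event's PSF shape, so
#' the subsequent model fit sees a clean spot. It also flattens the
#' position dependence of the ratiometric shot noise.
#'
#' @param stack A `ratio_stack` whose source movie carries its background.
#' @param background_map,flat_level Override the source movie's pre-landing
#'   background image and flat-interface level.
#' @return The corrected `ratio_stack`.
#' @export
correct_ratio_stack <- function(stack, background_map = NULL,
                                flat_level = NULL) {
  stopifnot(inherits(stack, "ratio_stack"))
  if (is.null(background_map)) background_map <- stack$source$background
  if (is.null(flat_level)) flat_level <- stack$source$flat_level
  if (is.null(background_map) || is.null(flat_level))
    stop("no background map available for the correction")
  fac <- sqrt(background_map / flat_level)
  out <- stack
  for (f in seq_len(dim(stack$ratio)[3]))
    out$ratio[, , f] <- stack$ratio[, , f] * fac
  if (!is.null(stack$sigma)) out$sigma <- stack$sigma * fac
  out
}

#' Local reflectivity correction of event contrasts
#'
#' The interferometric contrast scales with the inverse of the local
#' reference amplitude, so cover-glass roughness makes the measured contrast
#' depend on where a molecule lands. Multiplying each contrast by
#' `sqrt(I_bkg,local / I_bkg,flat)` removes that reflectivity dependence
#' (the unknown local phase contribution is left untouched and causes the
#' residual broadening). On a flat background the correction is the
#' identity; event coordinates are preserved.
#'
#' @param events Data.frame of detected events with `x`, `y`, `contrast`
#'   columns.
#' @param background_map Pre-landing mean intensity image of the movie.
#' @param flat_level Expected flat-interface intensity (same units).
#' @param half Half-width of the local background average (default 1: 3x3).
#' @return `events` with corrected `contrast`, the applied `correction`
#'   factor, and a logical `retained` flag (finite correction).
#' @export
reflectivity_correction <- function(events, background_map, flat_level,
                                    half = 1L) {
  if (nrow(events) == 0) {
    events$correction <- numeric(0)
    events$retained <- logical(0)
    return(events)
  }
  corr <- vapply(seq_len(nrow(events)), function(i) {
    loc <- mean(extract_patch(background_map, round(events$x[i]),
                              round(events$y[i]), half))
    sqrt(loc / flat_level)
  }, numeric(1))
  events$contrast <- events$contrast * corr
  events$correction <- corr
  events$retained <- is.finite(corr) & corr > 0
  events
}

#' Fit Gaussian peaks to a contrast or mass distribution
#'
#' Seeds peaks at the modes of a Gaussian kernel density estimate (default
#' bandwidth 2 kDa on the mass scale) and fits each peak by iteratively
#' trimmed normal moments (mean/sd re-estimated within +-2.5 sigma until
#' stable), which is robust to neighbouring peaks. Overlapping peaks are
#' flagged.
#'
#' @param values Event contrasts or masses.
#' @param bandwidth KDE bandwidth in the units of `values` (default 2).
#' @param min_weight Minimum KDE mode height relative to the largest mode.
#' @param max_peaks Maximum number of returned peaks.
#' @return An object of class `mass_histogram`: data.frame `peaks` with
#'   `mu`, `sigma`, `count`, `overlapping`; plus the raw `values` and
#'   `bandwidth`.
#' @export
fit_mass_peaks <- function(values, bandwidth = 2, min_weight = 0.1,
                           max_peaks = 10L) {
  stopifnot(length(values) >= 5)
  den <- stats::density(values, bw = bandwidth)
  y <- den$y
  modes <- which(diff(sign(diff(y))) == -2) + 1
  modes <- modes[y[modes] >= min_weight * max(y[modes])]
  modes <- modes[order(-y[modes])]
  modes <- utils::head(modes, max_peaks)
  mus <- sort(den$x[modes])
  peaks <- do.call(rbind, lapply(mus, function(mu0) {
    mu <- mu0
    sigma <- bandwidth
    for (it in 1:8) {
      w <- values[abs(values - mu) <= 2.5 * sigma]
      if (length(w) < 5) break
      mu <- mean(w)
      sigma <- stats::sd(w)
      if (!is.finite(sigma) || sigma == 0) { sigma <- bandwidth; break }
    }
    data.frame(mu = mu, sigma = sigma,
               count = sum(abs(values - mu) <= 2.5 * sigma))
  }))
  if (is.null(peaks) || nrow(peaks) == 0)
    stop("no peaks found in the distribution")
  peaks$overlapping <- FALSE
  if (nrow(peaks) > 1) {
    gap <- diff(peaks$mu)
    wide <- 2 * (peaks$sigma[-nrow(peaks)] + peaks$sigma[-1])
    ov <- gap < wide
    if (any(ov)) {
      peaks$overlapping[which(ov)] <- TRUE
      peaks$overlapping[which(ov) + 1] <- TRUE
      warning("overlapping peaks flagged; joint interpretation advised")
    }
  }
  structure(list(peaks = peaks, values = values, bandwidth = bandwidth),
            class = "mass_histogram")
}

#' Contrast-to-mass calibration from known species
#'
#' Least-squares line through the peak contrasts of calibrant species of
#' known mass. The slope is the contrast per kDa; masses of unknown events
#' follow by inverting the line.
#'
#' @param peak_contrasts Fitted peak contrasts of the calibrants.
#' @param masses_kda Their known masses (kDa).
#' @return An object of class `mass_calibration` with `slope`, `intercept`,
#'   `residuals`, and the calibrant table.
#' @export
calibrate_mass <- function(peak_contrasts, masses_kda) {
  if (length(peak_contrasts) < 2)
    stop("calibration is underdetermined with fewer than two peaks")
  fit <- stats::lm(peak_contrasts ~ masses_kda)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) warning("calibration slope is not positive")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 calibrants = data.frame(contrast = peak_contrasts,
                                         mass_kda = masses_kda)),
            class = "mass_calibration")
}

#' Convert contrasts to masses with a calibration
#'
#' @param calibration A `mass_calibration`.
#' @param contrasts Event contrasts.
#' @return Masses (kDa).
#' @export
contrast_to_mass <- function(calibration, contrasts) {
  (contrasts - calibration$intercept) / calibration$slope
}

#' Run the full analysis chain on a movie
#'
#' Ratiometric transform, event detection, PSF-model contrast fitting,
#' optional local reflectivity correction, and (when a calibration is
#' given) conversion to mass.
#'
#' @param stack A `frame_stack`.
#' @param n_avg Ratiometric window; defaults to the stack settings.
#' @param psf_model PSF model; defaults to [psf_model_theoretical()] of the
#'   stack's config.
#' @param mask_correction `"stack"` (default) applies the pixel-wise
#'   [correct_ratio_stack()] before detection and fitting, `"event"` rescales
#'   only the fitted contrasts via [reflectivity_correction()], `"none"`
#'   disables the correction. `TRUE`/`FALSE` map to `"stack"`/`"none"`.
#' @param calibration Optional `mass_calibration`.
#' @param ... Passed to [detect_events()].
#' @return A data.frame of events with fitted `contrast` (and `mass_kda`
#'   when calibrated).
#' @export
analyze_movie <- function(stack, n_avg = NULL, psf_model = NULL,
                          mask_correction = "stack", calibration = NULL, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  if (isTRUE(mask_correction)) mask_correction <- "stack"
  if (isFALSE(mask_correction)) mask_correction <- "none"
  mask_correction <- match.arg(mask_correction, c("stack", "event", "none"))
  rs <- ratiometric_stack(stack, n_avg)
  if (mask_correction == "stack") rs <- correct_ratio_stack(rs)
  cand <- detect_events(rs, ...)
  # events peaking at the stack edges never reach their full ratiometric
  # amplitude (truncated fade-in/out); drop them
  n_out <- dim(rs$ratio)[3]
  cand <- cand[cand$frame > 1 & cand$frame < n_out, ]
  if (nrow(cand) == 0) return(cand)
  if (is.null(psf_model)) psf_model <- psf_model_theoretical(stack$config)
  half <- min(3L, psf_model$half)
  fits <- lapply(seq_len(nrow(cand)), function(i) {
    patch <- extract_patch(rs$ratio[, , cand$frame[i]],
                           cand$x[i], cand$y[i], half)
    fit_event_contrast(patch, psf_model)
  })
  cand$contrast <- vapply(fits, `[[`, numeric(1), "contrast")
  cand$residual <- vapply(fits, `[[`, numeric(1), "residual")
  cand$converged <- vapply(fits, `[[`, logical(1), "converged")
  cand <- cand[cand$converged, ]
  if (mask_correction == "event") {
    cand <- reflectivity_correction(cand, stack$background, stack$flat_level)
    cand <- cand[cand$retained, ]
  }
  if (!is.null(calibration))
    cand$mass_kda <- contrast_to_mass(calibration, abs(cand$contrast))
  cand
}
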