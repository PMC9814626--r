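#' Optical model of the second-harmonic response
#'
#' Parameters of the forward model that turns per-leaflet surface potentials
#' into a coherent SH intensity. The detected intensity is
#' `gain * pump_intensity^2 * |chi2_top - chi2_bottom +
#' f3 * chi3_eff * (phi_top - phi_bottom)|^2` plus the incoherent
#' hyper-Rayleigh background. For a compositionally symmetric bilayer the
#' second-order terms cancel and only the potential difference radiates.
#'
#' @param chi2_top,chi2_bottom Surface second-order susceptibilities of the
#'   two leaflets (arbitrary units). Default 0 (symmetric composition).
#' @param chi3_eff Effective third-order susceptibility coupling the static
#'   surface potential to the response (arb. units per volt). Default 1.
#' @param f3 Interference factor in (0, 1]; tends to 1 in transmission
#'   geometry. Default 1.
#' @param pump_intensity Fundamental beam intensity (arb. units). Default 1.
#' @param gain Detected counts per unit squared polarization. Default 5000.
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(chi2_top = 0, chi2_bottom = 0, chi3_eff = 1,
                          f3 = 1, pump_intensity = 1, gain = 5000) {
  stopifnot(pump_intensity >= 0, gain > 0, f3 > 0, f3 <= 1)
  structure(
    list(chi2_top = chi2_top, chi2_bottom = chi2_bottom, chi3_eff = chi3_eff,
         f3 = f3, pump_intensity = pump_intensity, gain = gain),
    class = "optical_model"
  )
}

#' Configuration of the transient domain field
#'
#' Describes the population of short-lived ordered-water domains the
#' simulator plants on the membrane: a spatial Poisson process of Gaussian
#' potential patches inside a circular aperture, with memoryless per-frame
#' survival.
#'
#' @param mean_domain_count Expected number of live domains per frame on the
#'   top leaflet. Default 40.
#' @param domain_radius Characteristic domain radius in micrometres, defined
#'   as the FWHM of one domain's *intensity* footprint. Because intensity is
#'   quadratic in potential, the underlying Gaussian potential patch is a
#'   factor sqrt(2) wider. Default 1.5.
#' @param domain_potential Per-domain potential amplitude in volts (signed).
#'   Default -0.25.
#' @param amplitude_sd Standard deviation of per-domain amplitude draws
#'   (volts); 0 gives identical domains. Default 0.
#' @param lifetime_frames Expected persistence in frames; survival per frame
#'   is `exp(-1/lifetime_frames)` (memoryless). Values well below 1 give
#'   frame-to-frame independent placements. Default 0.3.
#' @param registry_coupling Probability that a top-leaflet domain is
#'   mirrored, with equal amplitude, on the bottom leaflet. Default 0.1.
#' @param aperture_diameter Circular field of view in micrometres.
#'   Default 100.
#' @param seed Integer random seed.
#' @return An object of class `domain_field_config`.
#' @export
domain_field_config <- function(mean_domain_count = 40, domain_radius = 1.5,
                                domain_potential = -0.25, amplitude_sd = 0,
                                lifetime_frames = 0.3, registry_coupling = 0.1,
                                aperture_diameter = 100, seed = 1L) {
  stopifnot(mean_domain_count >= 0, domain_radius > 0, amplitude_sd >= 0,
            lifetime_frames >= 0,
            registry_coupling >= 0, registry_coupling <= 1,
            aperture_diameter > 0)
  structure(
    list(mean_domain_count = mean_domain_count, domain_radius = domain_radius,
         domain_potential = domain_potential, amplitude_sd = amplitude_sd,
         lifetime_frames = lifetime_frames,
         registry_coupling = registry_coupling,
         aperture_diameter = aperture_diameter, seed = as.integer(seed)),
    class = "domain_field_config"
  )
}

#' Ground truth bundle for simulated stacks
#'
#' @param phi_top,phi_bottom Per-pixel leaflet potential fields in volts:
#'   a matrix (static scene) or a list of matrices (one per frame).
#' @param domain_catalog Data frame with one row per live domain per frame:
#'   `frame`, `y`, `x` (0-based pixel coordinates), `radius_um`,
#'   `amplitude_V`, `mirrored`.
#' @param hrs_level Mean hyper-Rayleigh background in counts.
#' @param mask Optional logical aperture mask; the coherent signal exists
#'   only inside it.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(phi_top, phi_bottom, domain_catalog = NULL,
                         hrs_level = 0, mask = NULL) {
  stopifnot(hrs_level >= 0)
  structure(
    list(phi_top = phi_top, phi_bottom = phi_bottom,
         domain_catalog = domain_catalog, hrs_level = hrs_level, mask = mask),
    class = "ground_truth"
  )
}

#' Bias sweep configuration
#'
#' @param bias_values Applied trans-membrane voltages in volts; at least 3
#'   distinct values (a parabola needs 3 points).
#' @param frames_per_bias Frames recorded at each bias. Default 1.
#' @return An object of class `bias_series_config`.
#' @export
bias_series_config <- function(bias_values, frames_per_bias = 1L) {
  if (length(unique(bias_values)) < 3)
    stop("need at least 3 distinct bias values")
  stopifnot(frames_per_bias >= 1)
  structure(list(bias_values = as.numeric(bias_values),
                 frames_per_bias = as.integer(frames_per_bias)),
            class = "bias_series_config")
}

#' Render noiseless SH intensity from leaflet potentials
#'
#' Forward model: the coherent intensity is the squared modulus of the sum of
#' the leaflet susceptibility difference and the potential-difference term,
#' scaled by gain and squared pump intensity, plus the incoherent
#' hyper-Rayleigh background. Identical leaflets (same susceptibility and
#' potential) radiate no coherent signal.
#'
#' @param optical An [optical_model()].
#' @param truth A [ground_truth()]; `phi_top`/`phi_bottom` may be matrices
#'   or per-frame lists of matrices.
#' @return A matrix (or list of matrices) of noiseless intensities in counts.
#' @export
render_intensity <- function(optical, truth) {
  stopifnot(inherits(optical, "optical_model"), inherits(truth, "ground_truth"))
  render1 <- function(pt, pb) {
    if (!identical(dim(pt), dim(pb)))
      stop("phi_top and phi_bottom grids do not match")
    amp <- (optical$chi2_top - optical$chi2_bottom) +
      optical$f3 * optical$chi3_eff * (pt - pb)
    coh <- optical$gain * optical$pump_intensity^2 * amp^2
    if (!is.null(truth$mask)) {
      if (!identical(dim(truth$mask), dim(pt)))
        stop("aperture mask grid does not match potential fields")
      coh <- coh * truth$mask
    }
    coh + truth$hrs_level
  }
  if (is.list(truth$phi_top)) {
    if (!is.list(truth$phi_bottom) ||
        length(truth$phi_top) != length(truth$phi_bottom))
      stop("phi_top and phi_bottom frame lists do not match")
    Map(render1, truth$phi_top, truth$phi_bottom)
  } else {
    render1(truth$phi_top, truth$phi_bottom)
  }
}

# Add one Gaussian potential patch (std sigma_px, 0-based center cy/cx) to a
# field, over a +/- 4 sigma window only.
add_patch <- function(field, cy, cx, sigma_px, amplitude) {
  nr <- nrow(field); nc <- ncol(field)
  w <- ceiling(4 * sigma_px)
  i <- max(1, floor(cy + 1 - w)):min(nr, ceiling(cy + 1 + w))
  j <- max(1, floor(cx + 1 - w)):min(nc, ceiling(cx + 1 + w))
  dy <- (i - 1) - cy
  dx <- (j - 1) - cx
  g <- exp(-outer(dy^2, dx^2, `+`) / (2 * sigma_px^2))
  field[i, j] <- field[i, j] + amplitude * g
  field
}

#' Simulate an SH image stack with ground truth
#'
#' Plants transient Gaussian-profile potential domains inside a circular
#' aperture (spatial Poisson process; memoryless per-frame survival with
#' probability `exp(-1/lifetime_frames)`; stationary expected count), renders
#' each frame through [render_intensity()], and optionally replaces pixel
#' values with Poisson draws to emulate shot noise. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [domain_field_config()].
#' @param optical An [optical_model()].
#' @param n_frames Number of frames to simulate.
#' @param shot_noise Apply Poisson shot noise? Default TRUE.
#' @param dim Image dimensions in pixels (rows, cols). Default c(128, 128).
#' @param pixel_size Pixel width in nanometres. Default 430.
#' @param exposure Frame integration time in milliseconds. Default 560.
#' @param hrs_level Mean hyper-Rayleigh background in counts. Default 50.
#' @return A list with `stack` (an [sh_stack()]) and `truth`
#'   (a [ground_truth()] with per-frame potential fields and domain catalog).
#' @export
simulate_stack <- function(config, optical = optical_model(), n_frames = 20,
                           shot_noise = TRUE, dim = c(128, 128),
                           pixel_size = 430, exposure = 560, hrs_level = 50) {
  stopifnot(inherits(config, "domain_field_config"), n_frames >= 1)
  radius_px <- config$domain_radius * 1000 / pixel_size
  if (radius_px < 1) {
    warning("domain radius below one pixel; clamped to 1 pixel")
    radius_px <- 1
  }
  # intensity-profile FWHM -> potential-patch std (intensity = potential^2)
  sigma_px <- sqrt(2) * radius_px / fwhm_factor()
  center <- (dim - 1) / 2
  ap_r <- config$aperture_diameter * 1000 / pixel_size / 2
  mask <- disk_mask(dim, center, ap_r)
  surv <- if (config$lifetime_frames > 0) exp(-1 / config$lifetime_frames) else 0

  with_seed(config$seed, {
    live <- NULL  # data.frame: y, x, amplitude, mirrored
    phi_t <- vector("list", n_frames)
    phi_b <- vector("list", n_frames)
    catalog <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      if (!is.null(live) && nrow(live) > 0)
        live <- live[stats::runif(nrow(live)) < surv, , drop = FALSE]
      lambda <- if (t == 1) config$mean_domain_count
                else config$mean_domain_count * (1 - surv)
      nb <- stats::rpois(1, lambda)
      if (nb > 0) {
        rr <- ap_r * sqrt(stats::runif(nb))
        th <- stats::runif(nb, 0, 2 * pi)
        births <- data.frame(
          y = center[1] + rr * sin(th),
          x = center[2] + rr * cos(th),
          amplitude = stats::rnorm(nb, config$domain_potential,
                                   config$amplitude_sd),
          mirrored = stats::runif(nb) < config$registry_coupling
        )
        live <- rbind(live, births)
      }
      pt <- matrix(0, dim[1], dim[2])
      pb <- matrix(0, dim[1], dim[2])
      if (!is.null(live) && nrow(live) > 0) {
        for (k in seq_len(nrow(live))) {
          pt <- add_patch(pt, live$y[k], live$x[k], sigma_px,
                          live$amplitude[k])
          if (live$mirrored[k])
            pb <- add_patch(pb, live$y[k], live$x[k], sigma_px,
                            live$amplitude[k])
        }
        catalog[[t]] <- data.frame(
          frame = t, y = live$y, x = live$x,
          radius_um = config$domain_radius,
          amplitude_V = live$amplitude, mirrored = live$mirrored
        )
      }
      pt[!mask] <- 0
      pb[!mask] <- 0
      phi_t[[t]] <- pt
      phi_b[[t]] <- pb
    }
    truth <- ground_truth(phi_t, phi_b,
                          domain_catalog = do.call(rbind, catalog),
                          hrs_level = hrs_level, mask = mask)
    frames <- render_intensity(optical, truth)
    if (shot_noise)
      frames <- lapply(frames, function(f)
        matrix(stats::rpois(length(f), f), nrow(f), ncol(f)))
    stack <- sh_stack(frames, pixel_size, exposure, aperture_mask = mask,
                      meta = list(seed = config$seed, hrs_level = hrs_level,
                                  simulated = TRUE))
    list(stack = stack, truth = truth)
  })
}

#' Simulate a bias calibration sweep
#'
#' Re-renders a static scene while adding an external trans-membrane bias
#' `U` to the leaflet potential difference, one set of frames per bias. The
#' coherent intensity is quadratic in `(dPhi + U)` with its minimum at
#' `U = -dPhi`, which is what the calibration fit exploits.
#'
#' @param config A [bias_series_config()].
#' @param optical An [optical_model()].
#' @param truth A [ground_truth()] with matrix-valued (static) potential
#'   fields.
#' @param shot_noise Apply Poisson shot noise? Default FALSE.
#' @param seed Seed used when `shot_noise` is TRUE. Default 1.
#' @param pixel_size,exposure Stack metadata, as in [simulate_stack()].
#' @return An [sh_stack()] whose `meta$bias` labels each frame's applied
#'   voltage.
#' @export
simulate_bias_series <- function(config, optical, truth, shot_noise = FALSE,
                                 seed = 1L, pixel_size = 430, exposure = 560) {
  stopifnot(inherits(config, "bias_series_config"),
            inherits(truth, "ground_truth"), is.matrix(truth$phi_top))
  frames <- list()
  labels <- numeric(0)
  for (U in config$bias_values) {
    shifted <- truth
    shifted$phi_top <- truth$phi_top + U
    img <- render_intensity(optical, shifted)
    for (r in seq_len(config$frames_per_bias)) {
      frames[[length(frames) + 1L]] <- img
      labels <- c(labels, U)
    }
  }
  if (shot_noise)
    frames <- with_seed(seed, lapply(frames, function(f)
      matrix(stats::rpois(length(f), f), nrow(f), ncol(f))))
  sh_stack(frames, pixel_size, exposure, aperture_mask = truth$mask,
           meta = list(bias = labels, simulated = TRUE))
}
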