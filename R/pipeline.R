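#' Ion preset configurations for the simulator
#'
#' Returns a [domain_field_config()] emulating the divalent-cation
#' conditions: domain potential amplitudes and spatial density descend in
#' the order Ca > Ba > Mg (domain means and SDs follow the measured
#' single-domain statistics; counts follow the observed density ordering).
#' The `"symmetric"` preset mirrors every domain onto the opposing leaflet
#' with equal amplitude, so the coherent signal cancels; `"calibration"`
#' is a domain-free uniform membrane used for bias sweeps.
#'
#' @param preset One of `"Ca"`, `"Ba"`, `"Mg"`, `"symmetric"`,
#'   `"calibration"`.
#' @param seed Random seed; default is preset-specific.
#' @param aperture_diameter Aperture in micrometres; fixtures default to a
#'   down-scaled 45 um field that fits a 128 px frame.
#' @return A [domain_field_config()].
#' @export
preset_config <- function(preset = c("Ca", "Ba", "Mg", "symmetric",
                                     "calibration"),
                          seed = NULL, aperture_diameter = 45) {
  preset <- match.arg(preset)
  base <- switch(preset,
    Ca = list(amp = -0.287, sd = 0.042, n = 25, coupling = 0.1, seed = 101L),
    Ba = list(amp = -0.170, sd = 0.040, n = 15, coupling = 0.1, seed = 102L),
    Mg = list(amp = -0.088, sd = 0.020, n = 8, coupling = 0.1, seed = 103L),
    symmetric = list(amp = -0.287, sd = 0, n = 25, coupling = 1, seed = 104L),
    calibration = list(amp = 0, sd = 0, n = 0, coupling = 0, seed = 105L)
  )
  domain_field_config(
    mean_domain_count = base$n, domain_radius = 1.5,
    domain_potential = base$amp, amplitude_sd = base$sd,
    lifetime_frames = 0.3, registry_coupling = base$coupling,
    aperture_diameter = aperture_diameter,
    seed = if (is.null(seed)) base$seed else seed
  )
}

#' Generate packaged demo fixtures
#'
#' Writes a small simulated acquisition (128 x 128 px, 20 frames) for one
#' preset: the image stack, a matching solution-only background stack, and
#' the ground truth, all as TIFF + YAML/CSV.
#'
#' @param preset See [preset_config()].
#' @param dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @param n_frames Frames to simulate. Default 20.
#' @return Invisibly, a named list of file paths (`stack`, `background`,
#'   `truth_dir`).
#' @export
make_fixtures <- function(preset, dir, seed = NULL, n_frames = 20) {
  config <- preset_config(preset, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  optical <- optical_model()
  sim <- simulate_stack(config, optical, n_frames = n_frames)
  bg_cfg <- config
  bg_cfg$mean_domain_count <- 0
  bg_cfg$seed <- config$seed + 5000L
  bg <- simulate_stack(bg_cfg, optical, n_frames = n_frames)
  paths <- list(
    stack = file.path(dir, paste0(preset, "_stack.tif")),
    background = file.path(dir, paste0(preset, "_background.tif")),
    truth_dir = file.path(dir, paste0(preset, "_truth"))
  )
  write_sh_stack(sim$stack, paths$stack)
  write_sh_stack(bg$stack, paths$background)
  write_ground_truth(sim$truth, paths$truth_dir)
  invisible(paths)
}

#' Default run configuration
#'
#' All physical constants of the study appear here once: 430 nm pixels,
#' 560 ms exposure, core permittivity 2.1 and thickness 4 nm, flexoelectric
#' showcase parameters f = 5e-19 C and kappa = 15 kT, temperature 298.15 K.
#'
#' @param simulation Either `list(preset = "Ca")` or a full
#'   [domain_field_config()]; mutually exclusive with `input`.
#' @param input Optional `list(stack =, background =)` of TIFF paths
#'   written in the package's dialect.
#' @param output_dir Where products are written; `NULL` for none.
#' @param sign Sign convention applied to the potential map. Default -1
#'   (divalent cations on the anionic leaflet lower the facing potential).
#' @param seed Seed for the calibration sweep noise and any simulation
#'   without its own seed.
#' @return A `run_config` list; see [run_pipeline()].
#' @export
run_config <- function(simulation = list(preset = "Ca"), input = NULL,
                       output_dir = NULL, sign = -1, seed = 1L) {
  structure(list(
    simulation = simulation,
    input = input,
    calibration = list(biases = seq(-0.2, 0.6, by = 0.2), phi_cal = -0.2),
    capacitor = list(epsilon = 2.1, thickness = 4e-9),
    flexo = list(f = 5e-19, kappa_kT = 15, thickness = 4e-9),
    segmentation = list(k = 2, min_size = 4),
    temperature = 298.15,
    pixel_size = 430, exposure = 560,
    n_frames = 20,
    sign = sign,
    output_dir = output_dir,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Per-domain peak potentials across a corrected stack
#'
#' Converts every frame to a potential map, segments domains on each frame's
#' magnitude map, and returns one signed peak potential per connected domain
#' per frame. Because the domains are shorter-lived than a frame, this
#' single-frame route preserves their amplitudes, which frame averaging
#' would dilute.
#'
#' @param stack A background-corrected [sh_stack()].
#' @param fit A [calibration_fit()][fit_bias_calibration()].
#' @param mask Logical aperture mask; defaults to the stack's.
#' @param sign Sign convention, see [intensity_to_potential()].
#' @param k,min_size Segmentation parameters, see [segment_domains()].
#' @param background_stats Optional reference statistics for the threshold.
#' @return Data frame with columns `frame` and `value_V` (signed peak
#'   potential of each domain).
#' @export
domain_potentials <- function(stack, fit, mask = NULL, sign = -1, k = 2,
                              min_size = 4, background_stats = NULL) {
  stopifnot(inherits(stack, "sh_stack"))
  if (is.null(mask)) mask <- stack$aperture_mask
  rows <- lapply(seq_len(n_frames(stack)), function(i) {
    pm <- intensity_to_potential(stack$frames[[i]], fit, sign = sign)
    seg <- segment_domains(abs(pm$values), mask, background_stats,
                           k = k, min_size = min_size)
    v <- domain_values(pm$values, seg)
    if (length(v) == 0) return(NULL)
    data.frame(frame = i, value_V = v)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(frame = integer(0), value_V = numeric(0))
  out
}

#' Table-style run summary from an average and per-domain potentials
#'
#' Derives the charge density, free energy and dissociation constant from
#' the aperture-averaged potential (the "Average" row) and from each
#' per-domain potential (the "Domain" rows: mean, SD, mean +/- SD range).
#'
#' @param avg_phi Aperture-averaged signed potential, volts.
#' @param domain_phi Vector of signed per-domain potentials, volts.
#' @param cap A [capacitor_model()].
#' @param const A [physical_constants()] object.
#' @return Data frame in the layout of [summarize_maps()].
#' @export
summarize_potentials <- function(avg_phi, domain_phi,
                                 cap = capacitor_model(),
                                 const = physical_constants()) {
  derive <- list(
    potential_mV = function(v) v * 1e3,
    sigma_mC_m2 = function(v) potential_to_charge(v, cap),
    dG_kT = function(v) as.numeric(potential_to_free_energy(v, const)),
    kd_M = function(v)
      free_energy_to_kd(as.numeric(potential_to_free_energy(v, const)))
  )
  rows <- lapply(names(derive), function(nm) {
    f <- derive[[nm]]
    avg <- f(avg_phi)
    if (length(domain_phi) > 0) {
      dv <- f(domain_phi)
      dm <- mean(dv); ds <- if (length(dv) > 1) stats::sd(dv) else 0
      data.frame(quantity = nm, average = avg, domain_mean = dm,
                 domain_sd = ds, domain_lo = dm - ds, domain_hi = dm + ds,
                 n_domains = length(dv))
    } else {
      data.frame(quantity = nm, average = avg, domain_mean = NA_real_,
                 domain_sd = NA_real_, domain_lo = NA_real_,
                 domain_hi = NA_real_, n_domains = 0L)
    }
  })
  do.call(rbind, rows)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — acquire (simulate or load), background
#' subtraction, autocorrelation analysis, bias calibration, potential /
#' charge / free-energy / dissociation mapping with domain statistics, and
#' flexoelectric topography — and optionally writes all products plus a run
#' log to `output_dir`. Deterministic for a fixed config and seed.
#'
#' @param config A [run_config()] (or a YAML file path with the same
#'   fields).
#' @return A list with the stack, masks, correlation estimates, calibration
#'   fit, maps, summary table and topography.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    base <- run_config()
    base[names(raw)] <- raw
    config <- base
  }
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$input)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulation' or 'input'")

  const <- physical_constants(config$temperature)
  cap <- capacitor_model(config$capacitor$epsilon, config$capacitor$thickness,
                         const)
  flexo <- flexo_model(config$flexo$f, config$flexo$kappa_kT,
                       config$flexo$thickness, const)
  optical <- optical_model()

  acquired <- stage("acquire", {
    if (has_sim) {
      dcfg <- if (inherits(config$simulation, "domain_field_config"))
        config$simulation
      else preset_config(config$simulation$preset,
                         seed = config$simulation$seed)
      sim <- simulate_stack(dcfg, optical, n_frames = config$n_frames,
                            pixel_size = config$pixel_size,
                            exposure = config$exposure)
      bgc <- dcfg; bgc$mean_domain_count <- 0; bgc$seed <- dcfg$seed + 5000L
      bg <- simulate_stack(bgc, optical, n_frames = config$n_frames,
                           pixel_size = config$pixel_size,
                           exposure = config$exposure)$stack
      list(stack = sim$stack, background = bg, truth = sim$truth,
           mask = sim$truth$mask)
    } else {
      stack <- read_sh_stack(config$input$stack)
      bg <- read_sh_stack(config$input$background)
      ap <- detect_aperture(average_frames(stack))
      stack$aperture_mask <- ap$mask
      list(stack = stack, background = bg, truth = NULL, mask = ap$mask)
    }
  })

  corrected <- stage("prep",
    subtract_background(acquired$stack, acquired$background))
  mask <- acquired$mask

  correlation <- stage("correlate", list(
    radius = estimate_radius(corrected, mask),
    lifetime = estimate_lifetime(corrected, mask)
  ))

  calib <- stage("calibrate", {
    d <- dim(corrected$frames[[1]])
    cal_truth <- ground_truth(
      phi_top = matrix(config$calibration$phi_cal, d[1], d[2]),
      phi_bottom = matrix(0, d[1], d[2]), hrs_level = 0)
    sweep <- simulate_bias_series(
      bias_series_config(config$calibration$biases), optical, cal_truth,
      seed = config$seed,
      pixel_size = config$pixel_size, exposure = config$exposure)
    fit_bias_calibration(as_calibration_series(sweep))
  })

  maps <- stage("map", {
    convention <- sprintf("sign %+d supplied from run chemistry", config$sign)
    phi_frames <- lapply(corrected$frames, function(f)
      intensity_to_potential(f, calib, sign = config$sign,
                             sign_convention = convention,
                             pixel_size = config$pixel_size)$values)
    frame_means <- vapply(phi_frames, function(p) mean(p[mask]), numeric(1))
    # domains are transient (sub-frame lifetimes): characterize them on
    # single-frame maps, where their full amplitude is visible, not on the
    # frame average that dilutes them
    dp <- domain_potentials(corrected, calib, mask, sign = config$sign,
                            k = config$segmentation$k,
                            min_size = config$segmentation$min_size)
    rep_i <- which.max(abs(frame_means))
    phi <- potential_map(phi_frames[[rep_i]], convention, config$pixel_size)
    tm <- thermo_maps(phi, cap, const)
    domains <- segment_domains(abs(tm$potential_mV), mask,
                               k = config$segmentation$k,
                               min_size = config$segmentation$min_size)
    summary <- summarize_potentials(mean(frame_means), dp$value_V, cap, const)
    list(phi = phi, representative_frame = rep_i, thermo = tm,
         domains = domains, domain_potentials = dp, summary = summary)
  })

  topo <- stage("topo", {
    H <- potential_to_curvature(maps$phi, flexo)
    h <- curvature_to_topography(H, mask, pixel_size = config$pixel_size)
    list(curvature = H, height = h)
  })

  result <- list(stack = corrected, mask = mask, truth = acquired$truth,
                 correlation = correlation, calibration = calib,
                 maps = maps, topography = topo, config = config)

  if (!is.null(config$output_dir))
    stage("write", write_pipeline_products(result, config$output_dir))
  result
}

write_pipeline_products <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sh_stack(result$stack, file.path(dir, "corrected_stack.tif"))
  write_map_tiff(result$maps$phi$values, file.path(dir, "potential.tif"),
                 units = "V",
                 extra = list(sign_convention = result$maps$phi$sign_convention))
  write_map_tiff(result$maps$thermo$sigma_mC_m2,
                 file.path(dir, "charge.tif"), units = "mC/m^2")
  write_map_tiff(result$maps$thermo$dG_kT,
                 file.path(dir, "free_energy.tif"), units = "kT")
  write_map_tiff(result$topography$curvature,
                 file.path(dir, "curvature.tif"), units = "1/nm")
  write_map_tiff(result$topography$height,
                 file.path(dir, "topography.tif"), units = "nm",
                 extra = list(boundary_condition = "h = 0 on aperture rim"))
  utils::write.csv(result$maps$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  products <- list.files(dir, full.names = TRUE)
  log <- list(
    package_version = as.character(utils::packageVersion("shgmap")),
    r_version = R.version.string,
    seed = result$config$seed,
    radius_um = result$correlation$radius$radius,
    lifetime_resolved = result$correlation$lifetime$resolved,
    checksums = as.list(tools::md5sum(products))
  )
  yaml::write_yaml(log, file.path(dir, "run_log.yml"))
  invisible(dir)
}
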