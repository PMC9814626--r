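#' Membrane potential to surface charge density
#'
#' Parallel-plate capacitor conversion across the low-dielectric hydrophobic
#' core: `dSigma0 = C * dPhi0` with `C = eps0 * epsilon / d`. The sign of
#' the charge map follows the sign of the potential map.
#'
#' @param phi A [potential_map()] or a numeric matrix/vector of potentials
#'   in volts.
#' @param cap A [capacitor_model()].
#' @return Charge density in mC/m^2, same shape as the input.
#' @export
#' @examples
#' potential_to_charge(-0.154)  # ~ -0.72 mC/m^2
potential_to_charge <- function(phi, cap = capacitor_model()) {
  stopifnot(inherits(cap, "capacitor_model"))
  v <- if (inherits(phi, "potential_map")) phi$values else phi
  cap$capacitance_per_area * v * 1e3
}

#' Membrane potential to electrostatic binding free energy
#'
#' `dG = 2 e |dPhi0| / kT`, reported as a positive magnitude in thermal
#' units (the factor 2 is the divalent ion's charge). The signed value is
#' retained in the `"signed"` attribute.
#'
#' @param phi A [potential_map()] or numeric matrix/vector in volts.
#' @param const A [physical_constants()] object (sets the temperature).
#' @return Free energy per ion in kT units (positive), with attribute
#'   `signed` carrying `2 e dPhi0 / kT` with its sign.
#' @export
#' @examples
#' potential_to_free_energy(-0.217)  # ~ 16.9 kT
potential_to_free_energy <- function(phi, const = physical_constants()) {
  stopifnot(inherits(const, "physical_constants"))
  v <- if (inherits(phi, "potential_map")) phi$values else phi
  signed <- 2 * const$elementary_charge * v / kT(const)
  out <- abs(signed)
  attr(out, "signed") <- signed
  out
}

#' Binding free energy to dissociation constant
#'
#' `dG = -RT ln(K_D)` evaluated per particle, i.e. `K_D = exp(-dG)` with
#' `dG` in kT units (numerically identical to the molar RT form). The
#' result is labelled in molar units by convention.
#'
#' @param dG Free energy in kT units (positive for favourable binding).
#' @return `exp(-dG)`, nominally in M.
#' @export
free_energy_to_kd <- function(dG) {
  attr(dG, "signed") <- NULL
  exp(-dG)
}

#' Segment bright domains in a map
#'
#' Median-smooths the map (3x3), thresholds at `background mean +
#' k * background SD`, and keeps connected components of at least
#' `min_size` pixels. Background statistics come from `background_stats`
#' (e.g. a domain-free reference region) when supplied, else from all
#' masked pixels.
#'
#' @param map Numeric matrix (any per-pixel quantity; pass magnitudes for
#'   signed maps).
#' @param mask Logical mask of valid pixels; must be non-empty.
#' @param background_stats Optional `list(mean =, sd =)` reference
#'   statistics.
#' @param k Threshold multiplier on the background SD. Default 2.
#' @param min_size Smallest kept component, pixels. Default 4.
#' @return Logical matrix of domain pixels (subset of `mask`).
#' @export
segment_domains <- function(map, mask = NULL, background_stats = NULL,
                            k = 2, min_size = 4) {
  stopifnot(is.matrix(map))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map), ncol(map))
  if (!any(mask)) stop("empty mask")
  sm <- median3(map)
  if (is.null(background_stats)) {
    background_stats <- list(mean = mean(sm[mask]), sd = stats::sd(sm[mask]))
  }
  thr <- background_stats$mean + k * background_stats$sd
  cand <- sm > thr & mask
  if (!any(cand)) return(cand)
  lab <- EBImage::bwlabel(EBImage::Image(cand))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_size)
  matrix(as.integer(lab) %in% keep, nrow(map), ncol(map))
}

#' Per-domain values of a map
#'
#' Labels the connected components of a domain mask and extracts one value
#' per component: its peak (the signed value of the largest-magnitude pixel,
#' default) or its pixel mean. A transient domain's characteristic potential
#' is its patch amplitude, which the peak samples; pixel means average over
#' the patch flanks and understate it.
#'
#' @param map Numeric matrix.
#' @param domain_mask Logical matrix from [segment_domains()].
#' @param statistic `"peak"` (default) or `"mean"`.
#' @return Numeric vector, one value per connected domain.
#' @export
domain_values <- function(map, domain_mask, statistic = c("peak", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(map), identical(dim(domain_mask), dim(map)))
  if (!any(domain_mask)) return(numeric(0))
  lab <- as.integer(EBImage::bwlabel(EBImage::Image(domain_mask)))
  vapply(seq_len(max(lab)), function(k) {
    v <- map[lab == k]
    if (statistic == "peak") v[which.max(abs(v))] else mean(v)
  }, numeric(1))
}

#' Table-style summary of potential and derived maps
#'
#' For each supplied quantity, reports the aperture-wide average and the
#' domain statistics: mean, SD, and the range `[mean - SD, mean + SD]` over
#' per-domain values (component peaks by default, see [domain_values()]).
#'
#' @param maps Named list of numeric matrices (e.g. `potential_mV`,
#'   `sigma_mC_m2`, `dG_kT`, `kd_M`), all the same shape.
#' @param domain_mask Logical matrix of domain pixels.
#' @param mask Logical aperture mask; default all pixels.
#' @param statistic Per-domain statistic, `"peak"` (default) or `"mean"`;
#'   see [domain_values()].
#' @return A data frame with one row per quantity: `quantity`, `average`,
#'   `domain_mean`, `domain_sd`, `domain_lo`, `domain_hi`, `n_domains`.
#'   Domain columns are `NA` when the domain mask is empty.
#' @export
summarize_maps <- function(maps, domain_mask, mask = NULL,
                           statistic = c("peak", "mean")) {
  stopifnot(is.list(maps), length(maps) > 0, !is.null(names(maps)))
  statistic <- match.arg(statistic)
  d <- dim(maps[[1]])
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  stopifnot(identical(dim(domain_mask), d))
  if (any(domain_mask & !mask)) stop("domain mask extends outside the aperture mask")
  rows <- lapply(names(maps), function(nm) {
    m <- maps[[nm]]
    stopifnot(identical(dim(m), d))
    avg <- mean(m[mask])
    dv <- domain_values(m, domain_mask, statistic)
    if (length(dv) > 0) {
      dm <- mean(dv); ds <- stats::sd(dv)
      if (is.na(ds)) ds <- 0
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

#' Full thermodynamic map bundle from a potential map
#'
#' Convenience wrapper computing the charge, free-energy and dissociation
#' constant maps in one call.
#'
#' @param phi A [potential_map()].
#' @param cap A [capacitor_model()].
#' @param const A [physical_constants()] object.
#' @return Named list of matrices: `potential_mV`, `sigma_mC_m2`, `dG_kT`,
#'   `kd_M`.
#' @export
thermo_maps <- function(phi, cap = capacitor_model(),
                        const = physical_constants()) {
  stopifnot(inherits(phi, "potential_map"))
  dg <- potential_to_free_energy(phi, const)
  attr(dg, "signed") <- NULL
  list(
    potential_mV = phi$values * 1e3,
    sigma_mC_m2 = potential_to_charge(phi, cap),
    dG_kT = dg,
    kd_M = free_energy_to_kd(dg)
  )
}
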