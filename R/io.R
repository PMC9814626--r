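# TIFF + YAML-sidecar I/O. tiff::writeTIFF stores [0,1] only, so every
# writer affine-scales data into [0,1] and records offset/scale in the
# sidecar; readers invert. Counts go to 16-bit pages, maps to 32-bit float.

#' Write an SH image stack as multi-page TIFF with YAML sidecar
#'
#' @param stack An [sh_stack()].
#' @param path Output path ending in `.tif`; the sidecar replaces the
#'   extension with `.yml`.
#' @return Invisibly, the sidecar path.
#' @export
write_sh_stack <- function(stack, path) {
  stopifnot(inherits(stack, "sh_stack"))
  top <- max(1, max(vapply(stack$frames, max, numeric(1))))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / top), path,
                  bits.per.sample = 16L, reduce = FALSE)
  side <- sub("\\.tif{1,2}$", ".yml", path)
  meta <- list(
    pixel_size_nm = stack$pixel_size,
    exposure_ms = stack$exposure,
    n_frames = n_frames(stack),
    counts_scale = top,
    bias = stack$meta$bias,
    seed = stack$meta$seed,
    background_subtracted = isTRUE(stack$meta$background_subtracted)
  )
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))], side)
  invisible(side)
}

#' Read an SH image stack written by [write_sh_stack()]
#'
#' @param path Path to the `.tif` file (a `.yml` sidecar must sit next to
#'   it).
#' @param aperture_mask Optional logical mask to attach.
#' @return An [sh_stack()].
#' @export
read_sh_stack <- function(path, aperture_mask = NULL) {
  side <- sub("\\.tif{1,2}$", ".yml", path)
  if (!file.exists(side)) stop("missing sidecar metadata file: ", side)
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) p * meta$counts_scale)
  m <- list(seed = meta$seed)
  if (!is.null(meta$bias)) m$bias <- as.numeric(meta$bias)
  if (isTRUE(meta$background_subtracted)) m$background_subtracted <- TRUE
  sh_stack(frames, meta$pixel_size_nm, meta$exposure_ms,
           aperture_mask = aperture_mask, meta = m)
}

#' Write a real-valued map as 32-bit float TIFF with YAML sidecar
#'
#' @param map Numeric matrix (any real values; potentials, charge,
#'   curvature, height...).
#' @param path Output `.tif` path.
#' @param units Unit string recorded in the sidecar.
#' @param extra Optional named list merged into the sidecar (e.g. boundary
#'   condition, model parameters).
#' @return Invisibly, the sidecar path.
#' @export
write_map_tiff <- function(map, path, units = "", extra = list()) {
  stopifnot(is.matrix(map))
  lo <- min(map); hi <- max(map)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((map - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  side <- sub("\\.tif{1,2}$", ".yml", path)
  yaml::write_yaml(c(list(units = units, offset = lo, scale = scale), extra),
                   side)
  invisible(side)
}

#' Read a map written by [write_map_tiff()]
#'
#' @param path Path to the `.tif` file.
#' @return Numeric matrix with attribute `units`.
#' @export
read_map_tiff <- function(path) {
  side <- sub("\\.tif{1,2}$", ".yml", path)
  if (!file.exists(side)) stop("missing sidecar metadata file: ", side)
  meta <- yaml::read_yaml(side)
  m <- tiff::readTIFF(path) * meta$scale + meta$offset
  attr(m, "units") <- meta$units
  m
}

#' Export a correlogram (and optional fit) as CSV + JSON summary
#'
#' @param corr A [correlogram()].
#' @param path Output `.csv` path; a `.json` summary is written alongside.
#' @param fit Optional `gaussian_fit` whose curve is tabulated in a `fit`
#'   column.
#' @return Invisibly, the CSV path.
#' @export
write_correlogram <- function(corr, path, fit = NULL) {
  stopifnot(inherits(corr, "correlogram"))
  df <- data.frame(lag = corr$lags, value = corr$values)
  summ <- list(kind = corr$kind, n_lags = length(corr$lags))
  if (!is.null(fit)) {
    df$fit <- fit$amplitude * exp(-corr$lags^2 / (2 * fit$width^2)) + fit$offset
    summ <- c(summ, fit[c("amplitude", "width", "offset", "fwhm",
                          "residual_rms")])
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(summ, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the simulator's ground truth (float TIFFs + CSV catalog)
#'
#' @param truth A [ground_truth()] with per-frame potential fields.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pt <- truth$phi_top; pb <- truth$phi_bottom
  if (is.matrix(pt)) { pt <- list(pt); pb <- list(pb) }
  mean_t <- Reduce(`+`, pt) / length(pt)
  mean_b <- Reduce(`+`, pb) / length(pb)
  write_map_tiff(mean_t, file.path(dir, "phi_top_mean.tif"), units = "V")
  write_map_tiff(mean_b, file.path(dir, "phi_bottom_mean.tif"), units = "V")
  if (!is.null(truth$domain_catalog))
    utils::write.csv(truth$domain_catalog,
                     file.path(dir, "domain_catalog.csv"), row.names = FALSE)
  yaml::write_yaml(list(hrs_level = truth$hrs_level),
                   file.path(dir, "truth.yml"))
  invisible(dir)
}
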