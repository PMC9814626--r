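#' Bias calibration series
#'
#' One (averaged) background-corrected image per applied trans-membrane
#' bias voltage.
#'
#' @param biases Applied voltages in volts; at least 3 distinct.
#' @param images List of numeric matrices, one per bias, same shape.
#' @return An object of class `calibration_series`.
#' @export
calibration_series <- function(biases, images) {
  if (length(unique(biases)) < 3)
    stop("need at least 3 distinct bias values")
  stopifnot(length(biases) == length(images),
            all(vapply(images, is.matrix, logical(1))))
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("calibration images must share dimensions")
  structure(list(biases = as.numeric(biases), images = images),
            class = "calibration_series")
}

#' Extract a calibration series from a simulated bias sweep
#'
#' Averages the frames recorded at each bias label of a stack produced by
#' [simulate_bias_series()] (or loaded with matching `meta$bias` labels).
#'
#' @param stack An [sh_stack()] whose `meta$bias` labels every frame.
#' @return A [calibration_series()].
#' @export
as_calibration_series <- function(stack) {
  stopifnot(inherits(stack, "sh_stack"))
  b <- stack$meta$bias
  if (is.null(b) || length(b) != n_frames(stack))
    stop("stack has no per-frame bias labels")
  ub <- unique(b)
  imgs <- lapply(ub, function(U) {
    fr <- stack$frames[b == U]
    Reduce(`+`, fr) / length(fr)
  })
  calibration_series(ub, imgs)
}

#' Fit the quadratic bias calibration
#'
#' The coherent SH intensity is quadratic in the total trans-membrane
#' potential, so sweeping an external bias `U` traces the parabola
#' `I(U) = scale * (U - vertex)^2 + baseline`; the vertex sits where the
#' bias cancels the membrane's own potential difference (vertex = -dPhi0 of
#' the calibration membrane), and `scale` converts counts to volts squared.
#'
#' @param series A [calibration_series()].
#' @param mask Logical mask over which intensities are averaged (global
#'   mode); default all pixels.
#' @param per_pixel Fit one parabola per pixel instead of one global fit?
#'   Noisier; default FALSE.
#' @return An object of class `calibration_fit` with `scale` (counts/V^2),
#'   `baseline` (counts), `vertex` (V) — matrices in per-pixel mode — and
#'   `per_pixel` flag.
#' @export
fit_bias_calibration <- function(series, mask = NULL, per_pixel = FALSE) {
  stopifnot(inherits(series, "calibration_series"))
  U <- series$biases
  X <- cbind(1, U, U^2)
  if (qr(X)$rank < 3) stop("degenerate bias design: biases are collinear")
  if (per_pixel) {
    Y <- vapply(series$images, as.vector, numeric(length(series$images[[1]])))
    B <- t(qr.solve(X, t(Y)))            # n_pixels x 3
    a2 <- B[, 3]
    if (any(a2 <= 0)) stop("non-quadratic response at ", sum(a2 <= 0), " pixel(s)")
    d <- dim(series$images[[1]])
    vertex <- matrix(-B[, 2] / (2 * a2), d[1], d[2])
    baseline <- matrix(B[, 1] - B[, 2]^2 / (4 * a2), d[1], d[2])
    scale <- matrix(a2, d[1], d[2])
  } else {
    y <- vapply(series$images, function(m) {
      if (is.null(mask)) mean(m) else mean(m[mask])
    }, numeric(1))
    b <- qr.solve(X, y)
    if (b[3] <= 0) stop("non-quadratic response: fitted curvature is not positive")
    scale <- unname(b[3])
    vertex <- unname(-b[2] / (2 * b[3]))
    baseline <- unname(b[1] - b[2]^2 / (4 * b[3]))
  }
  structure(list(scale = scale, baseline = baseline, vertex = vertex,
                 per_pixel = per_pixel),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  if (x$per_pixel) {
    cat("Per-pixel bias calibration fit\n")
  } else {
    cat(sprintf("Bias calibration: scale %.4g counts/V^2, baseline %.4g counts, vertex %.4g V\n",
                x$scale, x$baseline, x$vertex))
  }
  invisible(x)
}

#' Membrane potential map
#'
#' @param values Matrix of signed trans-membrane potential differences
#'   (top minus bottom leaflet) in volts.
#' @param sign_convention Free-text record of how the sign was assigned
#'   (intensity alone is sign-blind).
#' @param pixel_size Pixel width in nanometres.
#' @return An object of class `potential_map`.
#' @export
potential_map <- function(values, sign_convention = "unspecified",
                          pixel_size = 430) {
  stopifnot(is.matrix(values))
  structure(list(values = values, sign_convention = sign_convention,
                 pixel_size = pixel_size),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("Potential map %d x %d px: mean %.1f mV, range [%.1f, %.1f] mV (%s)\n",
              nrow(x$values), ncol(x$values), mean(v) * 1e3,
              min(v) * 1e3, max(v) * 1e3, x$sign_convention))
  invisible(x)
}

#' Convert corrected SH intensity to a membrane potential map
#'
#' Inverts the calibrated quadratic response pixelwise:
#' `|dPhi0| = sqrt(max(I - baseline, 0) / scale)`. Pixels at or below the
#' baseline map to zero. The modulus-squared detection discards the sign, so
#' a sign (scalar or per-pixel matrix) must be supplied from chemical
#' context (e.g. negative for divalent cations on an anionic leaflet).
#'
#' @param image Background-corrected 2D intensity (counts).
#' @param fit A [calibration_fit()].
#' @param sign +1 or -1, or a matrix of signs. Default -1.
#' @param sign_convention Text recorded in the map metadata.
#' @param pixel_size Pixel width in nanometres. Default 430.
#' @return A [potential_map()].
#' @export
intensity_to_potential <- function(image, fit, sign = -1,
                                   sign_convention = "supplied per run",
                                   pixel_size = 430) {
  stopifnot(is.matrix(image), inherits(fit, "calibration_fit"))
  if (any(fit$scale <= 0)) stop("calibration scale must be positive")
  mag <- sqrt(pmax(image - fit$baseline, 0) / fit$scale)
  potential_map(sign * mag, sign_convention, pixel_size)
}
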