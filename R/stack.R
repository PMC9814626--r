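#' SH image stack container
#'
#' Time-ordered stack of 2D photon-count images with acquisition metadata.
#' This is the common currency of the pipeline: the simulator produces one,
#' the preparation and correlation stages consume and return them.
#'
#' @param frames A list of numeric matrices (one per frame) or a single
#'   matrix; all frames must share dimensions and be non-negative.
#' @param pixel_size Physical pixel width in nanometres. Default 430.
#' @param exposure Per-frame integration time in milliseconds. Default 560.
#' @param aperture_mask Optional logical matrix marking pixels inside the
#'   aperture; same shape as the frames.
#' @param meta Optional named list of free-form metadata (seed, bias labels,
#'   provenance flags).
#' @return An object of class `sh_stack`.
#' @export
sh_stack <- function(frames, pixel_size = 430, exposure = 560,
                     aperture_mask = NULL, meta = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, is.matrix, logical(1))))
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share the same dimensions")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("frames must be non-negative photon counts")
  stopifnot(pixel_size > 0, exposure > 0)
  if (!is.null(aperture_mask)) {
    stopifnot(is.logical(aperture_mask), identical(dim(aperture_mask), d))
  }
  structure(
    list(frames = frames, pixel_size = pixel_size, exposure = exposure,
         aperture_mask = aperture_mask, meta = meta),
    class = "sh_stack"
  )
}

#' @export
print.sh_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("SH image stack: %d frame(s) of %d x %d px (%.0f nm/px, %.0f ms/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$exposure))
  if (!is.null(x$aperture_mask))
    cat(sprintf("  aperture mask: %d px inside\n", sum(x$aperture_mask)))
  if (isTRUE(x$meta$background_subtracted))
    cat("  background-corrected\n")
  invisible(x)
}

#' @export
length.sh_stack <- function(x) length(x$frames)

#' Number of frames in a stack
#' @param stack An [sh_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

#' Subtract the hyper-Rayleigh scattering background
#'
#' Removes the incoherent bulk-solution second-harmonic background (measured
#' on a membrane-free solution image) from every frame, clipping the result
#' at zero so downstream square-root intensity conversions stay defined.
#'
#' @param stack An [sh_stack()].
#' @param bg A numeric matrix, a list of matrices, or an [sh_stack()]; if
#'   more than one frame, the background is frame-averaged before
#'   subtraction (subtraction and averaging commute in the mean).
#' @return A new `sh_stack` with corrected frames and
#'   `meta$background_subtracted = TRUE`. Subtracting twice raises an error.
#' @export
subtract_background <- function(stack, bg) {
  stopifnot(inherits(stack, "sh_stack"))
  if (isTRUE(stack$meta$background_subtracted))
    stop("background already subtracted from this stack")
  if (inherits(bg, "sh_stack")) bg <- bg$frames
  if (is.matrix(bg)) bg <- list(bg)
  d <- dim(stack$frames[[1]])
  if (!all(vapply(bg, function(f) identical(dim(f), d), logical(1))))
    stop("background shape does not match stack frames")
  bgm <- Reduce(`+`, bg) / length(bg)
  out <- lapply(stack$frames, function(f) pmax(f - bgm, 0))
  meta <- stack$meta
  meta$background_subtracted <- TRUE
  sh_stack(out, stack$pixel_size, stack$exposure, stack$aperture_mask, meta)
}

#' Average the first n frames of a stack
#'
#' @param stack An [sh_stack()].
#' @param n Number of leading frames to average; defaults to all.
#' @return A numeric matrix, the arithmetic mean of the first `n` frames.
#' @export
average_frames <- function(stack, n = n_frames(stack)) {
  stopifnot(inherits(stack, "sh_stack"))
  if (n < 1 || n > n_frames(stack)) stop("n out of range")
  Reduce(`+`, stack$frames[seq_len(n)]) / n
}

#' Detect the circular aperture in an image
#'
#' Thresholds the image at the between-class-variance-maximizing (Otsu)
#' level, takes the largest bright connected region, fits a circle to its
#' boundary by least squares, and returns the fitted disk eroded by 2 pixels
#' to exclude the aperture rim.
#'
#' @param image A numeric matrix (typically a frame average).
#' @param min_area Smallest acceptable region, in pixels. Default 100.
#' @return A list with `mask` (logical matrix), `center` (row, col; 0-based
#'   pixel units) and `radius` (pixels, before erosion).
#' @export
detect_aperture <- function(image, min_area = 100) {
  stopifnot(is.matrix(image), length(image) > 0)
  rng <- range(image)
  if (diff(rng) == 0) {
    if (rng[1] <= 0) stop("no aperture found: image is constant")
    # uniformly bright: everything is "inside"; erode 2 px from the border
    nr <- nrow(image); nc <- ncol(image)
    mask <- matrix(FALSE, nr, nc)
    mask[3:(nr - 2), 3:(nc - 2)] <- TRUE
    return(list(mask = mask, center = c((nr - 1) / 2, (nc - 1) / 2),
                radius = Inf))
  }
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bright <- norm > thr
  lab <- EBImage::bwlabel(EBImage::Image(bright))
  tab <- tabulate(as.integer(lab))
  if (length(tab) == 0 || max(tab) < min_area)
    stop("no aperture found: no bright region larger than ", min_area, " px")
  region <- as.integer(lab) == which.max(tab)
  region <- matrix(region, nrow(image), ncol(image))
  # boundary = region pixels with a non-region 4-neighbour (or on the edge)
  nr <- nrow(region); nc <- ncol(region)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- region
  interior <- padded[1:nr, 2:(nc + 1)] & padded[3:(nr + 2), 2:(nc + 1)] &
    padded[2:(nr + 1), 1:nc] & padded[2:(nr + 1), 3:(nc + 2)]
  boundary <- which(region & !interior, arr.ind = TRUE)
  # algebraic (Kasa) circle fit: x^2+y^2 = a*x + b*y + c
  y <- boundary[, 1] - 1; x <- boundary[, 2] - 1
  A <- cbind(x, y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  mask <- disk_mask(dim(image), c(cy, cx), r - 2)
  list(mask = mask, center = c(cy, cx), radius = r)
}
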