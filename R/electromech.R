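#' Membrane potential to flexoelectric curvature
#'
#' Converse flexoelectric response: the trans-membrane field `E = dPhi0/d`
#' bends the membrane to a total curvature `H = f E / (2 kappa) =
#' f dPhi0 / (2 kappa d)`.
#'
#' @param phi A [potential_map()] or numeric matrix/vector in volts.
#' @param model A [flexo_model()].
#' @return Curvature in 1/nm, same shape as the input; attribute `model`
#'   carries the parameter snapshot.
#' @export
#' @examples
#' potential_to_curvature(0.368)  # ~0.37 nm^-1 at f = 5e-19 C, kappa = 15 kT
potential_to_curvature <- function(phi, model = flexo_model()) {
  stopifnot(inherits(model, "flexo_model"))
  if (model$kappa <= 0) stop("bending modulus must be positive")
  v <- if (inherits(phi, "potential_map")) phi$values else phi
  H <- model$f * v / (2 * model$kappa * model$thickness) * 1e-9  # 1/m -> 1/nm
  attr(H, "model") <- model
  H
}

#' Curvature bounds over a flexocoefficient / bending-modulus box
#'
#' `H = f dPhi0 / (2 kappa d)` is monotone in both `f` (increasing) and
#' `kappa` (decreasing), so the extrema over a rectangular parameter box sit
#' at its corners: the minimum at (f_min, kappa_max) and the maximum at
#' (f_max, kappa_min).
#'
#' @param phi_value Potential difference in volts (magnitude used).
#' @param f_range Flexocoefficient range in coulombs, `c(min, max)`.
#' @param kappa_range Bending modulus range in kT units, `c(min, max)`.
#' @param thickness Membrane thickness in metres. Default 4e-9.
#' @param const A [physical_constants()] object.
#' @return Named numeric `c(H_min =, H_max =)` in 1/nm.
#' @export
curvature_bounds <- function(phi_value, f_range = c(1e-21, 1e-18),
                             kappa_range = c(10, 20), thickness = 4e-9,
                             const = physical_constants()) {
  stopifnot(length(f_range) == 2, length(kappa_range) == 2)
  if (f_range[1] > f_range[2] || kappa_range[1] > kappa_range[2])
    stop("parameter ranges must be ordered (min, max)")
  stopifnot(f_range[1] > 0, kappa_range[1] > 0, thickness > 0)
  H <- function(f, kap_kT)
    f * abs(phi_value) / (2 * kap_kT * kT(const) * thickness) * 1e-9
  c(H_min = H(f_range[1], kappa_range[2]),
    H_max = H(f_range[2], kappa_range[1]))
}

#' Reconstruct membrane topography from a curvature map
#'
#' In the small-slope limit the height field obeys the Poisson equation
#' `laplacian(h) = 2 H` (total curvature read as twice the mean curvature).
#' Solved on the masked pixels with a 5-point Laplacian and a pinned rim
#' (`h = 0` on and outside the mask boundary) by sparse Cholesky
#' factorization.
#'
#' @param H Curvature matrix in 1/nm (e.g. from
#'   [potential_to_curvature()]).
#' @param mask Logical matrix of membrane pixels (simply connected).
#' @param pixel_size Pixel width in nanometres. Default 430.
#' @return Matrix of heights in nm (0 outside the mask), with attribute
#'   `boundary_condition = "h = 0 on aperture rim"`.
#' @export
curvature_to_topography <- function(H, mask, pixel_size = 430) {
  stopifnot(is.matrix(H), is.logical(mask), identical(dim(mask), dim(H)))
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  if (max(lab) > 1) stop("mask is disconnected (", max(lab), " components)")
  nr <- nrow(H); nc <- ncol(H)
  idx <- matrix(0L, nr, nc)
  inside <- which(mask)
  idx[inside] <- seq_along(inside)
  n <- length(inside)
  io <- ((inside - 1) %% nr) + 1   # row
  jo <- ((inside - 1) %/% nr) + 1  # col
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ni <- io + d[1]; nj <- jo + d[2]
    valid <- ni >= 1 & ni <= nr & nj >= 1 & nj <= nc
    nb <- rep(0L, n)
    nb[valid] <- idx[cbind(ni[valid], nj[valid])]
    has <- nb > 0L
    ii <- c(ii, seq_len(n)[has]); jj <- c(jj, nb[has])
    xx <- c(xx, rep(-1, sum(has)))
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, rep(4, n)), dims = c(n, n))
  b <- -2 * H[inside] * pixel_size^2   # h [nm], spacing [nm], H [1/nm]
  h <- as.numeric(Matrix::solve(A, b))
  out <- matrix(0, nr, nc)
  out[inside] <- h
  attr(out, "boundary_condition") <- "h = 0 on aperture rim"
  out
}
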