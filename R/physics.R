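#' Physical constants bundle
#'
#' CODATA values used throughout the charge, free-energy and curvature
#' conversions. Temperature is the only tunable; it enters both the thermal
#' energy `kT` and the conversion of bending moduli quoted in kT units.
#'
#' @param temperature Absolute temperature in kelvin. Default 298.15 K.
#' @return An object of class `physical_constants`: a list with
#'   `vacuum_permittivity` (F/m), `elementary_charge` (C), `boltzmann` (J/K),
#'   `gas_constant` (J/(mol K)) and `temperature` (K).
#' @export
#' @examples
#' const <- physical_constants()
#' kT(const)  # thermal energy in joules at 298.15 K
physical_constants <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  structure(
    list(
      vacuum_permittivity = 8.8541878128e-12,
      elementary_charge   = 1.602176634e-19,
      boltzmann           = 1.380649e-23,
      gas_constant        = 8.314462618,
      temperature         = temperature
    ),
    class = "physical_constants"
  )
}

#' Thermal energy in joules
#'
#' @param const A [physical_constants()] object.
#' @return `k_B * T` in joules.
#' @export
kT <- function(const = physical_constants()) {
  const$boltzmann * const$temperature
}

#' Parallel-plate capacitor model of the membrane core
#'
#' The hydrophobic core of the bilayer is treated as a parallel-plate
#' capacitor of relative permittivity `epsilon` and thickness `d`, so that a
#' trans-membrane potential difference maps to a surface charge density via
#' the area capacitance `C = eps0 * epsilon / d`.
#'
#' @param epsilon Relative dielectric constant of the hydrophobic core
#'   (dimensionless). Default 2.1.
#' @param thickness Core thickness `d` in metres. Default 4e-9 (4 nm).
#' @param const A [physical_constants()] object.
#' @return An object of class `capacitor_model` with fields `epsilon`,
#'   `thickness` and the derived `capacitance_per_area` (F/m^2).
#' @export
#' @examples
#' cap <- capacitor_model()
#' cap$capacitance_per_area  # ~4.65e-3 F/m^2
capacitor_model <- function(epsilon = 2.1, thickness = 4e-9,
                            const = physical_constants()) {
  stopifnot(epsilon > 0, thickness > 0)
  structure(
    list(
      epsilon = epsilon,
      thickness = thickness,
      capacitance_per_area = const$vacuum_permittivity * epsilon / thickness
    ),
    class = "capacitor_model"
  )
}

#' Flexoelectric membrane model
#'
#' Parameter bundle for the converse flexoelectric effect: a trans-membrane
#' field `E = dPhi / d` bends the membrane to total curvature
#' `H = f E / (2 kappa)`, with `f` the flexocoefficient and `kappa` the
#' bending modulus.
#'
#' @param f Flexocoefficient in coulombs. Default 5e-19 C.
#' @param kappa_kT Bending modulus in units of kT. Default 15.
#' @param thickness Membrane (core) thickness in metres. Default 4e-9.
#' @param const A [physical_constants()] object; sets the temperature used to
#'   convert `kappa_kT` to joules.
#' @return An object of class `flexo_model` with fields `f` (C), `kappa` (J),
#'   `kappa_kT`, `thickness` (m).
#' @export
flexo_model <- function(f = 5e-19, kappa_kT = 15, thickness = 4e-9,
                        const = physical_constants()) {
  stopifnot(f > 0, kappa_kT > 0, thickness > 0)
  structure(
    list(
      f = f,
      kappa_kT = kappa_kT,
      kappa = kappa_kT * kT(const),
      thickness = thickness,
      temperature = const$temperature
    ),
    class = "flexo_model"
  )
}

#' @export
print.capacitor_model <- function(x, ...) {
  cat("Parallel-plate capacitor model\n")
  cat(sprintf("  epsilon: %.3g   d: %.3g nm   C: %.4g F/m^2\n",
              x$epsilon, x$thickness * 1e9, x$capacitance_per_area))
  invisible(x)
}

#' @export
print.flexo_model <- function(x, ...) {
  cat("Flexoelectric model\n")
  cat(sprintf("  f: %.3g C   kappa: %.3g kT (%.3g J)   d: %.3g nm\n",
              x$f, x$kappa_kT, x$kappa, x$thickness * 1e9))
  invisible(x)
}
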