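#' Thermal energy in pN nm
#'
#' Boltzmann constant times temperature, expressed in piconewton nanometres.
#' Uses the exact SI value `k_B = 1.380649e-23` J/K; 1 J = 1e21 pN nm.
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @return Thermal energy kBT in pN nm (about 4.114 pN nm at 298.15 K).
#' @export
kbt_pN_nm <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  1.380649e-23 * temperature_K * 1e21
}

#' Convert between mechanical and thermal units
#'
#' Forces are converted between pN and kBT/nm, torques (and energies) between
#' pN nm and kBT.  Round trips are identities to machine precision.
#'
#' @param value Numeric vector to convert.
#' @param from,to Unit names: one of `"pN"`, `"kBT_per_nm"` for forces, or
#'   `"pN.nm"`, `"kBT"` for torques/energies.
#' @param temperature_K Temperature used for the thermal energy scale.
#' @return Converted numeric vector.
#' @export
#' @examples
#' convert_units(4.114, "pN.nm", "kBT")  # about 1
convert_units <- function(value, from, to, temperature_K = 298.15) {
  kbt <- kbt_pN_nm(temperature_K)
  force_units <- c("pN", "kBT_per_nm")
  torque_units <- c("pN.nm", "kBT")
  if (from %in% force_units && to %in% force_units) {
    if (from == to) return(value)
    if (from == "pN") value / kbt else value * kbt
  } else if (from %in% torque_units && to %in% torque_units) {
    if (from == to) return(value)
    if (from == "pN.nm") value / kbt else value * kbt
  } else {
    stop("unknown unit pair: '", from, "' -> '", to, "'")
  }
}

#' Mechanical constraint (force and torque)
#'
#' Bundles the stretching force and the applied torque acting on the DNA ends.
#' Internally both are stored in thermal units: force in kBT/nm, torque in
#' kBT (so the energy terms `-f z` and `-2 pi tau dLk` are dimensionless).
#'
#' @param f_pN Force in pN (along the fixed laboratory z axis, must be >= 0).
#' @param tau_pN_nm Torque in pN nm (sign gives over-/underwinding).
#' @param f,tau Alternatively, dimensionless force (kBT/nm) and torque (kBT).
#' @param temperature_K Temperature used for unit conversion.
#' @return Object of class `mech_constraint` with elements `f` (kBT/nm),
#'   `tau` (kBT), `f_pN`, `tau_pN_nm`, `temperature_K`.
#' @export
mech_constraint <- function(f_pN = NULL, tau_pN_nm = NULL,
                            f = NULL, tau = NULL, temperature_K = 298.15) {
  kbt <- kbt_pN_nm(temperature_K)
  if (is.null(f)) f <- if (is.null(f_pN)) 0 else f_pN / kbt
  if (is.null(tau)) tau <- if (is.null(tau_pN_nm)) 0 else tau_pN_nm / kbt
  stopifnot(length(f) == 1L, length(tau) == 1L, is.finite(f), is.finite(tau))
  if (f < 0) stop("force must be non-negative (it defines the +z axis)")
  structure(list(f = f, tau = tau, f_pN = f * kbt, tau_pN_nm = tau * kbt,
                 temperature_K = temperature_K),
            class = "mech_constraint")
}

#' @export
print.mech_constraint <- function(x, ...) {
  cat(sprintf("mechanical constraint: f = %.4g pN (%.4g kBT/nm), tau = %.4g pN.nm (%.4g kBT)\n",
              x$f_pN, x$f, x$tau_pN_nm, x$tau))
  invisible(x)
}
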