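#' Physical constants for gating energetics
#'
#' Returns the constants used throughout the package: the Faraday constant
#' both in kcal mol^-1 V^-1 (for free-energy arithmetic, `F_kcal`) and in
#' C mol^-1 (`F_C`), the gas constant in kcal mol^-1 K^-1, the elementary
#' charge in C, and the working temperature.  The derived thermal voltage
#' `kT_mV = RT/F` (in mV) sets the voltage scale of every Boltzmann
#' expression in the package; at the default 295.15 K it is about 25.4 mV.
#'
#' Oocyte recordings are typically made at room temperature; 295.15 K
#' (22 degrees C) is the package default and can be overridden everywhere a
#' temperature enters.
#'
#' @param temperature_K temperature in kelvin.
#' @return list with `F_kcal`, `F_C`, `R_kcal`, `e0`, `T`, and `kT_mV`.
#' @examples
#' phys_constants()$kT_mV  # ~25.43 mV
#' @export
phys_constants <- function(temperature_K = 295.15) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  F_kcal <- 23.061     # kcal mol^-1 V^-1
  R_kcal <- 1.9872e-3  # kcal mol^-1 K^-1
  list(
    F_kcal = F_kcal,
    F_C    = 96485,
    R_kcal = R_kcal,
    e0     = 1.602176634e-19,
    T      = temperature_K,
    kT_mV  = 1000 * R_kcal * temperature_K / F_kcal
  )
}

#' Two-state Boltzmann open probability
#'
#' Equilibrium open probability `1 / (1 + exp(-z (V - Vd) / kT))` for a
#' channel with effective valence `z` (elementary charges) and midpoint
#' `Vd` (mV).
#'
#' @param V voltage(s), mV.
#' @param z effective gating valence, e0 units.
#' @param Vd midpoint voltage, mV.
#' @param temperature_K temperature, K.
#' @return open probability in (0, 1), same length as `V`.
#' @export
boltzmann_po <- function(V, z, Vd, temperature_K = 295.15) {
  kT <- phys_constants(temperature_K)$kT_mV
  1 / (1 + exp(-z * (V - Vd) / kT))
}
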