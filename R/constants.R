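#' Physical constants for metabolic-rate standardisation
#'
#' Returns the constants used throughout the rate-correction and
#' coefficient-conversion chain: Boltzmann's constant in eV/K, the default
#' activation energy, the oxycalorific conversion (20 J per mL O2), and the
#' default body temperatures substituted for endotherms with no reported
#' measurement temperature (mammals 37 C, birds 39 C).
#'
#' @param activation_energy_eV Activation energy Ea in electron-volts.
#'   0.63 eV is the default used for the updated coefficient chain; 0.6 eV
#'   is the value used when recalculating the legacy coefficients.
#' @return A named list with elements `boltzmann_k`, `activation_energy_Ea`,
#'   `joules_per_ml_O2`, `mammal_body_temp_K`, `bird_body_temp_K`.
#' @examples
#' physical_constants()$boltzmann_k
#' @export
physical_constants <- function(activation_energy_eV = 0.63) {
  stopifnot(is.numeric(activation_energy_eV), activation_energy_eV > 0)
  list(
    boltzmann_k        = 8.617333e-5,   # eV / K
    activation_energy_Ea = activation_energy_eV,
    joules_per_ml_O2   = 20,
    mammal_body_temp_K = 310.15,        # 37 C
    bird_body_temp_K   = 312.15         # 39 C
  )
}

#' @keywords internal
celsius_to_kelvin <- function(x) x + 273.15

#' Metabolic group levels recognised across the package
#' @keywords internal
metabolic_groups <- function() {
  c("producer", "ecto_invertebrate", "ecto_vertebrate", "endo_vertebrate")
}
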