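#' Physical constants and unit conversions
#'
#' Internal unit conventions: lengths in Angstrom, energies in kJ/mol,
#' temperature in Kelvin.  Pressures are accepted in atm and converted once
#' to kJ/(mol A^3); surface tensions are accepted in dyn/cm (= mN/m) and
#' converted once to kJ/(mol A^2).  All conversions live here so that every
#' other module works in a single consistent unit system.
#'
#' @format NULL
#' @name units
NULL

#' Boltzmann constant in kJ/(mol K)
#' @rdname units
#' @export
KB_KJ_MOL_K <- 0.008314462618

#' One atmosphere expressed in kJ/(mol A^3)
#' @rdname units
#' @export
ATM_TO_KJ_MOL_A3 <- 101325 * 6.02214076e23 * 1e-33

#' One dyn/cm (mN/m) expressed in kJ/(mol A^2)
#' @rdname units
#' @export
DYN_CM_TO_KJ_MOL_A2 <- 1e-3 * 6.02214076e23 * 1e-23

#' Thermal energy k_B T
#'
#' @param temperature temperature in K
#' @return k_B T in kJ/mol
#' @export
kBT <- function(temperature) {
  stopifnot(temperature > 0)
  KB_KJ_MOL_K * temperature
}

#' Vapor--liquid surface tension of water
#'
#' Standard correlation (IAPWS form) for the surface tension of water along
#' the saturation line, used to transfer a reference surface tension between
#' nearby temperatures.
#'
#' @param temperature temperature in K
#' @return surface tension in dyn/cm
#' @export
water_surface_tension <- function(temperature) {
  Tc <- 647.096
  tau <- 1 - temperature / Tc
  stopifnot(tau > 0)
  235.8 * tau^1.256 * (1 - 0.625 * tau)
}

#' Temperature-correct a model surface tension
#'
#' Shifts a surface tension reported at `t_ref` to `temperature` using the
#' experimental temperature dependence of water's vapor--liquid surface
#' tension (the model value is assumed to track the experimental slope over
#' small temperature differences).
#'
#' @param gamma_ref reference surface tension (dyn/cm)
#' @param t_ref temperature at which `gamma_ref` applies (K)
#' @param temperature target temperature (K)
#' @return corrected surface tension in dyn/cm
#' @export
corrected_surface_tension <- function(gamma_ref, t_ref, temperature) {
  gamma_ref + water_surface_tension(temperature) - water_surface_tension(t_ref)
}
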