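#' @title Thermal kinetics
#' @description Temperature dependencies used throughout the cell model:
#'   Arrhenius scaling of enzymatic turnover, super-exponential scaling of
#'   photosystem heat damage, and the temperature-dependent upper bound on
#'   the transporter-to-membrane-lipid ratio.
#' @name thermal
NULL

#' Boltzmann's constant in eV per Kelvin.
#' @keywords internal
BOLTZMANN_EV <- 8.617e-5

.check_temperature <- function(T, name = "T") {
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop(sprintf("'%s' must be a positive absolute temperature in Kelvin", name),
         call. = FALSE)
  invisible(T)
}

#' Arrhenius temperature factor
#'
#' Dimensionless multiplier on a reaction rate at absolute temperature `T`
#' relative to a reference temperature `T_ref`:
#' `gamma = exp[(E_a / R) (1/T_ref - 1/T)]` with `R` Boltzmann's constant in
#' eV/K. The factor exceeds 1 exactly when `E_a > 0` and `T > T_ref`.
#'
#' @param E_a Activation energy (eV), `>= 0`.
#' @param T Absolute temperature (K).
#' @param T_ref Reference absolute temperature (K).
#' @return Dimensionless factor (vectorized over `T`).
#' @examples
#' arrhenius_factor(0.7, 303.15, 293.15)
#' @export
arrhenius_factor <- function(E_a, T, T_ref) {
  .check_temperature(T); .check_temperature(T_ref, "T_ref")
  if (any(E_a < 0)) stop("'E_a' must be non-negative", call. = FALSE)
  exp((E_a / BOLTZMANN_EV) * (1 / T_ref - 1 / T))
}

#' Temperature-corrected turnover rate
#'
#' Scales a maximum turnover rate `k_ref` (defined at `T_ref`) to temperature
#' `T` by the Arrhenius factor. Photochemical photon capture is temperature
#' independent; pass `temperature_independent = TRUE` to return `k_ref`
#' unchanged for such reactions.
#'
#' @param k_ref Maximum turnover at the reference temperature (min^-1), `>= 0`.
#' @param E_a Activation energy (eV).
#' @param T Absolute temperature (K).
#' @param T_ref Reference absolute temperature (K).
#' @param temperature_independent If `TRUE` the rate is not scaled.
#' @return Rate at `T` (min^-1).
#' @export
rate_at_temperature <- function(k_ref, E_a, T, T_ref,
                                temperature_independent = FALSE) {
  if (any(k_ref < 0)) stop("'k_ref' must be non-negative", call. = FALSE)
  if (isTRUE(temperature_independent)) return(k_ref)
  k_ref * arrhenius_factor(E_a, T, T_ref)
}

#' Photosystem heat-damage rate
#'
#' Maximum damage rate at temperature `T`, pivoting at the damage reference
#' temperature `T_d`: `k_d = k_ref_d * exp[(E_d / R)(1/T_d - 1/T)]`. The
#' deactivation energy `E_d` is typically several eV, so damage grows
#' super-exponentially above `T_d` and is negligible well below it.
#'
#' @param k_ref_d Damage rate at `T_d` (min^-1), `>= 0`.
#' @param E_d Deactivation energy (eV), `>= 0`.
#' @param T Absolute temperature (K).
#' @param T_d Damage reference temperature (K).
#' @return Damage rate at `T` (min^-1).
#' @export
damage_rate <- function(k_ref_d, E_d, T, T_d) {
  .check_temperature(T); .check_temperature(T_d, "T_d")
  if (any(k_ref_d < 0)) stop("'k_ref_d' must be non-negative", call. = FALSE)
  if (any(E_d < 0)) stop("'E_d' must be non-negative", call. = FALSE)
  k_ref_d * exp((E_d / BOLTZMANN_EV) * (1 / T_d - 1 / T))
}

#' Temperature-dependent transporter-to-lipid membrane bound
#'
#' Upper bound on the ratio of membrane transporters to membrane lipids,
#' `M_min + (M_max - M_min) (T_max - T) / (T_max - T_min)`. The bound falls
#' linearly with temperature: warmer membranes are built from saturated
#' lipids that pack tightly, so more lipid is needed per transporter to keep
#' membrane integrity.
#'
#' @param T Absolute temperature (K).
#' @param M_min,M_max Minimum and maximum allowed ratio, `0 <= M_min <= M_max`.
#' @param T_min,T_max Temperature range (K) over which the linear law applies.
#' @param clamp If `TRUE`, temperatures outside `[T_min, T_max]` are clamped
#'   to the range instead of raising an error.
#' @return Maximum allowed `p_tr / c_lm` (dimensionless).
#' @export
membrane_ratio_bound <- function(T, M_min, M_max, T_min, T_max, clamp = FALSE) {
  .check_temperature(T)
  if (M_min < 0 || M_max < M_min) stop("need 0 <= M_min <= M_max", call. = FALSE)
  if (T_min >= T_max) stop("need T_min < T_max", call. = FALSE)
  if (isTRUE(clamp)) {
    T <- pmin(pmax(T, T_min), T_max)
  } else if (any(T < T_min | T > T_max)) {
    stop(sprintf("temperature outside membrane sweep range [%.2f, %.2f] K",
                 T_min, T_max), call. = FALSE)
  }
  M_min + (M_max - M_min) * (T_max - T) / (T_max - T_min)
}

#' Q10 equivalent of an activation energy
#'
#' Factor by which an Arrhenius-scaled rate increases over a 10 K rise
#' starting at `T_low`. Diagnostic helper for comparing activation energies
#' with the Q10 values conventionally reported for metabolic rates.
#'
#' @param E_a Activation energy (eV).
#' @param T_low Lower absolute temperature (K).
#' @return Dimensionless Q10.
#' @export
q10_equivalent <- function(E_a, T_low) {
  .check_temperature(T_low, "T_low")
  arrhenius_factor(E_a, T_low + 10, T_low)
}

#' Convert degrees Celsius to Kelvin
#' @param x Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert Kelvin to degrees Celsius
#' @param x Temperature in Kelvin.
#' @return Temperature in degrees Celsius.
#' @export
kelvin_to_celsius <- function(x) x - 273.15
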