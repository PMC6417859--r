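#' Rate constant perturbation
#'
#' Small increments to the reaction rate k and relaxation rate r, used to
#' probe the temperature sensitivity of the triplet yield (both rates are
#' expected to increase with temperature).
#'
#' @param dk Increment to k, s\eqn{^{-1}}.
#' @param dr Increment to r, s\eqn{^{-1}}.
#' @return An object of class `rate_perturbation`.
#' @examples
#' rate_perturbation(dk = 1e3, dr = 0)
#' @export
rate_perturbation <- function(dk = 0, dr = 0) {
  structure(list(dk = dk, dr = dr), class = "rate_perturbation")
}

#' Temperature effect on the triplet yield
#'
#' Fractional change of the yield under a rate perturbation,
#' \deqn{Te_{\Delta k, \Delta r} = \frac{\Phi_T(k + \Delta k, r + \Delta r) -
#'   \Phi_T(k, r)}{\Phi_T(k, r)},}
#' at a fixed static field with no ELF component.  For small perturbations
#' the two single-rate effects are additive to first order.  A 0.1% per
#' degree C change in both rates is a plausible scale for weakly activated
#' processes (see [arrhenius_activation_energy()]).
#'
#' @param system A [radical_pair_system()].
#' @param kin A [reaction_kinetics()] giving the unperturbed rates.
#' @param pert A [rate_perturbation()]; the perturbed rates must satisfy
#'   `k + dk > 0` and `r + dr >= 0`.
#' @param B0_uT Static field, uT.
#' @param cache Optional spectral cache (internal reuse).
#' @return The signed fractional change (dimensionless; multiply by 1e6 for
#'   ppm).
#' @examples
#' Te <- temperature_effect(rp_preset("FAD-Z"),
#'                          reaction_kinetics(k = 1e6, r = 1e6),
#'                          rate_perturbation(dk = 1e3), B0_uT = 50)
#' Te * 1e6  # ppm
#' @export
temperature_effect <- function(system, kin, pert, B0_uT = 50, cache = NULL) {
  stopifnot(inherits(kin, "reaction_kinetics"),
            inherits(pert, "rate_perturbation"))
  k2 <- kin$k + pert$dk
  r2 <- kin$r + pert$dr
  if (k2 <= 0) stop("perturbed k must be positive", call. = FALSE)
  if (r2 < 0) stop("perturbed r must be non-negative", call. = FALSE)
  if (is.null(cache)) cache <- .spectral_cache(system)
  spec <- .cached_spec(cache, B0_uT)
  phi0 <- .phi_from_spec(spec, kin$k, kin$r)
  (.phi_from_spec(spec, k2, r2) - phi0) / phi0
}

#' Arrhenius activation energy from a fractional rate change per kelvin
#'
#' For Arrhenius behaviour, rate \eqn{\propto \exp(-E_a / RT)}, the logarithmic
#' temperature derivative of the rate is \eqn{d \ln k / dT = E_a / (R T^2)},
#' so a measured fractional change per kelvin converts to
#' \eqn{E_a = R T^2 \, (d \ln k / dT)}.
#'
#' @param fractional_change_per_K Fractional rate change per kelvin,
#'   K\eqn{^{-1}} (e.g. 0.001 for 0.1% per degree C).
#' @param T_K Absolute temperature, K (> 0).  Default 310.15 K (37 C).
#' @return A list with `Ea_J_mol` (J mol\eqn{^{-1}}) and `Ea_over_RT`
#'   (dimensionless).
#' @examples
#' arrhenius_activation_energy(0.001)  # ~0.80 kJ/mol, ~0.31 RT
#' @export
arrhenius_activation_energy <- function(fractional_change_per_K,
                                        T_K = 310.15) {
  if (T_K <= 0) stop("'T_K' must be positive", call. = FALSE)
  R <- .const$R
  Ea <- R * T_K^2 * fractional_change_per_K
  list(Ea_J_mol = Ea, Ea_over_RT = Ea / (R * T_K))
}
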