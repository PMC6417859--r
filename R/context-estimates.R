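# Order-of-magnitude context estimates that situate the simulated yield
# changes: Larmor precession timescales, orientational averaging of the ELF
# amplitude, superparamagnetic alignment, and geomagnetic gradients.

#' Electron Larmor precession frequency and period
#'
#' @param B_uT Magnetic flux density, uT (>= 0).
#' @return A list with `frequency_Hz` (\eqn{\gamma_e B / 2\pi}) and
#'   `period_s` (infinite at B = 0).
#' @examples
#' larmor(50)  # ~1.4 MHz, ~700 ns
#' @export
larmor <- function(B_uT) {
  if (B_uT < 0) stop("'B_uT' must be non-negative", call. = FALSE)
  f <- .const$gamma_e * B_uT * 1e-6 / (2 * pi)
  list(frequency_Hz = f, period_s = if (f > 0) 1 / f else Inf)
}

#' Effective total field range for a randomly oriented ELF field
#'
#' When the ELF field is randomly oriented rather than parallel to the static
#' field, only its component along the static field matters (to first order,
#' since B1 << B0), reducing the effective amplitude by the mean projection
#' factor f.  Two averaging conventions are provided:
#' \describe{
#'   \item{`uniform_angle`}{mean of \eqn{\cos\theta} for \eqn{\theta} uniform
#'     on (0, \eqn{\pi/2}): \eqn{f = 2/\pi \approx 0.64}}
#'   \item{`solid_angle`}{mean of \eqn{|\cos\theta|} under isotropic
#'     (\eqn{\sin\theta}) weighting: \eqn{f = 1/2}}
#' }
#' Because the ELF effect scales as amplitude squared, assuming parallel
#' alignment overestimates it by \eqn{f^{-2}} (about 2.4 for the
#' uniform-angle convention, 4 for solid-angle).
#'
#' @param B0_uT Static field, uT.
#' @param B1_uT ELF peak amplitude, uT (`B1 < B0`).
#' @param convention `"uniform_angle"` (default) or `"solid_angle"`.
#' @return A list with `min_uT`, `max_uT` (the range `B0 -+ f B1`), `factor`
#'   (f) and `overestimate_factor` (\eqn{f^{-2}}; reported as 1 when B1 = 0).
#' @examples
#' randomly_oriented_effective_field_range(50, 1)  # ~49.36 to ~50.64 uT
#' @export
randomly_oriented_effective_field_range <- function(
    B0_uT, B1_uT, convention = c("uniform_angle", "solid_angle")) {
  convention <- match.arg(convention)
  if (B1_uT >= B0_uT) stop("requires B1 < B0", call. = FALSE)
  f <- if (convention == "uniform_angle") 2 / pi else 0.5
  list(min_uT = B0_uT - f * B1_uT,
       max_uT = B0_uT + f * B1_uT,
       factor = f,
       overestimate_factor = if (B1_uT > 0) f^-2 else 1)
}

#' Magnetic-to-thermal energy ratio of a superparamagnetic particle
#'
#' Ratio \eqn{m B / k_B T} of the interaction energy of a particle's magnetic
#' moment with a field to the thermal energy.  For ferritin (instantaneous
#' moment ~300 Bohr magnetons) in a 1 uT field at body temperature the ratio
#' is ~1e-6, so alignment of the moment by an ELF field -- and hence any
#' amplification of the field near the particle -- is negligible.
#'
#' @param moment_in_bohr_magnetons Magnetic moment, in units of \eqn{\mu_B}.
#' @param B_uT Magnetic flux density, uT.
#' @param T_K Absolute temperature, K (> 0).
#' @return The dimensionless ratio.
#' @examples
#' superparamagnet_alignment_ratio(300, 1, 310)  # ~6.5e-7
#' @export
superparamagnet_alignment_ratio <- function(moment_in_bohr_magnetons, B_uT,
                                            T_K = 310) {
  if (T_K <= 0) stop("'T_K' must be positive", call. = FALSE)
  moment_in_bohr_magnetons * .const$bohr_magneton * B_uT * 1e-6 /
    (.const$k_B * T_K)
}

#' Distance along a meridian equivalent to a static field change
#'
#' The geomagnetic field strength varies from ~65 uT at the magnetic poles to
#' ~25 uT at the magnetic equator over a quarter of the Earth's
#' circumference, an average meridional gradient of roughly 4 nT per km.
#' This converts a small static field change into the distance one would
#' travel north-south to experience it.
#'
#' @param delta_B_nT Field change, nT.
#' @param B_pole_uT Field at the magnetic pole, uT.
#' @param B_equator_uT Field at the magnetic equator, uT (`< B_pole_uT`).
#' @param circumference_km Circumference of the Earth, km.
#' @return A list with `gradient_nT_per_km` and `distance_km`.
#' @examples
#' geomagnetic_distance_equivalent(10)  # ~2.5 km
#' @export
geomagnetic_distance_equivalent <- function(delta_B_nT, B_pole_uT = 65,
                                            B_equator_uT = 25,
                                            circumference_km = 40000) {
  if (circumference_km <= 0) stop("circumference must be positive", call. = FALSE)
  if (B_pole_uT <= B_equator_uT) {
    stop("requires B_pole > B_equator", call. = FALSE)
  }
  gradient <- (B_pole_uT - B_equator_uT) * 1e3 / (circumference_km / 4)
  if (gradient == 0) stop("zero gradient", call. = FALSE)
  list(gradient_nT_per_km = gradient,
       distance_km = abs(delta_B_nT) / gradient)
}
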