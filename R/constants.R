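#' Physical constants used throughout the package
#'
#' Returns the set of physical constants the simulator relies on.  The
#' electron g-value is fixed at the free-electron value 2.0023; the remaining
#' constants are CODATA 2018 values.  The electron gyromagnetic ratio is
#' derived as \eqn{\gamma_e = g_e \mu_B / \hbar} and is the single conversion
#' factor between magnetic flux density and angular frequency: fields and
#' hyperfine couplings are stored in \eqn{\mu}T everywhere and converted to
#' rad s\eqn{^{-1}} only when the Hamiltonian is assembled.
#'
#' @return A named list with components
#'   \item{g_e}{electron g-value, dimensionless (2.0023)}
#'   \item{bohr_magneton}{Bohr magneton \eqn{\mu_B}, J T\eqn{^{-1}}}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{k_B}{Boltzmann constant, J K\eqn{^{-1}}}
#'   \item{R}{molar gas constant, J mol\eqn{^{-1}} K\eqn{^{-1}}}
#'   \item{gamma_e}{electron gyromagnetic ratio, rad s\eqn{^{-1}} T\eqn{^{-1}}}
#' @examples
#' const <- physical_constants()
#' # Larmor frequency in a 50 uT field, ~1.4 MHz:
#' const$gamma_e * 50e-6 / (2 * pi)
#' @export
physical_constants <- function() {
  g_e <- 2.0023
  bohr_magneton <- 9.2740100783e-24
  hbar <- 1.054571817e-34
  list(
    g_e = g_e,
    bohr_magneton = bohr_magneton,
    hbar = hbar,
    k_B = 1.380649e-23,
    R = 8.314462618,
    gamma_e = g_e * bohr_magneton / hbar
  )
}

# module-level copy so hot paths avoid rebuilding the list
.const <- physical_constants()

# microtesla -> angular frequency (rad/s)
.uT_to_rad_s <- function(uT) .const$gamma_e * uT * 1e-6
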