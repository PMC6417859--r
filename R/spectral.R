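#' Spectral decomposition of the spin Hamiltonian
#'
#' Diagonalises the spin Hamiltonian at a given static field and computes the
#' singlet-projector weight matrix \eqn{w_{mn} = |\langle m | P_S | n
#' \rangle|^2} in the eigenbasis.  This is the reusable core of every yield
#' calculation: the eigenfrequencies \eqn{\omega_m} and weights depend on the
#' system and the field only, so a single decomposition serves any number of
#' reaction/relaxation rate combinations (the main performance lever for
#' lifetime sweeps).
#'
#' @param system A [radical_pair_system()].
#' @param B_uT Static magnetic flux density, uT (>= 0).
#' @return An object of class `spectral_decomposition`: a list with
#'   \item{field_uT}{the field at which it was computed}
#'   \item{omegas}{eigenfrequencies \eqn{\omega_m}, rad s\eqn{^{-1}}}
#'   \item{weights}{symmetric non-negative matrix \eqn{w_{mn}}; its total sum
#'     equals M because \eqn{P_S} is a projector of rank M}
#'   \item{domega}{precomputed difference matrix \eqn{\omega_m - \omega_n}}
#'   \item{M}{number of nuclear spin configurations}
#' @examples
#' sp <- spectral_decomposition(rp_preset("FAD-Z"), 50)
#' sum(sp$weights)  # 9
#' @export
spectral_decomposition <- function(system, B_uT) {
  H <- build_hamiltonian(system, B_uT)
  es <- eigen(H, symmetric = TRUE)
  V <- es$vectors
  PS_eig <- Conj(t(V)) %*% singlet_projector(system) %*% V
  w <- Re(PS_eig * Conj(PS_eig))
  w <- (w + t(w)) / 2  # symmetrise away rounding noise
  structure(
    list(field_uT = B_uT, omegas = es$values, weights = w,
         domega = outer(es$values, es$values, "-"), M = system$M),
    class = "spectral_decomposition"
  )
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf(
    "<spectral_decomposition> dim %d at B = %g uT; M = %d, sum(w) = %.6f\n",
    length(x$omegas), x$field_uT, x$M, sum(x$weights)))
  invisible(x)
}

#' Triplet probability of a singlet-born radical pair
#'
#' In the absence of relaxation the probability that the pair is triplet at
#' time t is
#' \deqn{p_T'(t) = 1 - \frac{1}{M} \sum_{m,n} w_{mn}
#'   \cos[(\omega_m - \omega_n) t],}
#' the oscillations reflecting the coherent superposition state the pair is
#' born in.  Exponential relaxation towards the statistical 1:3
#' singlet:triplet mixture gives
#' \deqn{p_T(t) = \frac{3}{4} + \left(p_T'(t) - \frac{3}{4}\right) e^{-rt}.}
#'
#' @param spec A [spectral_decomposition()].
#' @param t Time(s) since pair creation, s (>= 0); vectorised.
#' @param r Spin relaxation rate constant, s\eqn{^{-1}} (>= 0).
#' @return Probability value(s) in \[0, 1\]; 0 at t = 0.
#' @examples
#' sp <- spectral_decomposition(rp_preset("FAD-Z"), 50)
#' triplet_probability(sp, c(0, 1e-7), r = 1e6)
#' @export
triplet_probability <- function(spec, t, r = 0) {
  stopifnot(inherits(spec, "spectral_decomposition"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (r < 0) stop("'r' must be non-negative", call. = FALSE)
  vapply(t, function(ti) {
    pT_coh <- 1 - sum(spec$weights * cos(spec$domega * ti)) / spec$M
    0.75 + (pT_coh - 0.75) * exp(-r * ti)
  }, numeric(1))
}

#' Ultimate triplet yield of the radical pair reaction
#'
#' The fraction of pairs that react through the triplet channel once all
#' pairs have reacted, \eqn{\Phi_T = k \int_0^\infty p_T(t) e^{-kt} dt},
#' evaluated in closed form from the spectral decomposition:
#' \deqn{\Phi_T = \frac{3}{4} + \frac{k}{4(k+r)} - \frac{1}{M} \sum_{m,n}
#'   w_{mn} \frac{k(k+r)}{(k+r)^2 + (\omega_m - \omega_n)^2}.}
#' Diagonal (\eqn{m = n}) terms enter naturally with \eqn{\Delta\omega = 0};
#' the expression is smooth at degeneracies.
#'
#' @param spec A [spectral_decomposition()].
#' @param kin A [reaction_kinetics()] object (k > 0, r >= 0).
#' @return The yield \eqn{\Phi_T \in [0, 1]}.
#' @examples
#' sp <- spectral_decomposition(rp_preset("FAD-Z"), 50)
#' triplet_yield(sp, reaction_kinetics(tau = 1e-6, r = 1e6))
#' @export
triplet_yield <- function(spec, kin) {
  stopifnot(inherits(spec, "spectral_decomposition"),
            inherits(kin, "reaction_kinetics"))
  .phi_from_spec(spec, kin$k, kin$r)
}

# hot path shared by sweeps: plain doubles, no class dispatch
.phi_from_spec <- function(spec, k, r) {
  kr <- k + r
  0.75 + k / (4 * kr) -
    sum(spec$weights * (k * kr / (kr^2 + spec$domega^2))) / spec$M
}

# ---- spectral cache -------------------------------------------------------
# Decompositions depend on (system, B) only; sweeps over kinetics reuse them.

.spectral_cache <- function(system) {
  env <- new.env(parent = emptyenv())
  env$system <- system
  env
}

.cached_spec <- function(cache, B_uT) {
  key <- sprintf("B%.12g", B_uT)
  spec <- cache[[key]]
  if (is.null(spec)) {
    spec <- spectral_decomposition(cache$system, B_uT)
    assign(key, spec, envir = cache)
  }
  spec
}

# yield at field B for rates (k, r), through the cache
.phi_cached <- function(cache, B_uT, k, r) {
  .phi_from_spec(.cached_spec(cache, B_uT), k, r)
}
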