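# Brute-force reference implementations.  These deliberately avoid the
# spectral shortcuts of the main code path so the two routes can validate
# each other: time propagation uses matrix exponentials of the Hamiltonian,
# and the yield is obtained by numerical time-domain quadrature instead of
# the closed-form Lorentzian sum.  They are slow by design and intended for
# testing, not production sweeps.

# exp(A) for a complex matrix via the real 2n x 2n embedding
# [[Re A, -Im A], [Im A, Re A]], delegating to Matrix::expm
.expm_complex <- function(A) {
  n <- nrow(A)
  E <- rbind(cbind(Re(A), -Im(A)), cbind(Im(A), Re(A)))
  X <- as.matrix(Matrix::expm(Matrix::Matrix(E)))
  X[seq_len(n), seq_len(n)] + 1i * X[n + seq_len(n), seq_len(n)]
}

#' Triplet probability by direct unitary propagation
#'
#' Propagates the singlet-born ensemble (density operator \eqn{\rho_0 = P_S /
#' M}, the uniform mixture over nuclear configurations) under
#' \eqn{U(t) = e^{-iHt}} and evaluates \eqn{p_T(t) = 1 - \mathrm{Tr}[P_S
#' \rho(t)]} at each requested time, with a fresh matrix exponential per time
#' point.  No relaxation is applied (this is the coherent probability).
#' Serves as an independent cross-check of [triplet_probability()].
#'
#' @param system A [radical_pair_system()].
#' @param B_uT Static field, uT.
#' @param times Vector of times, s (>= 0).
#' @return An object of class `propagation_result`: list with `times` and
#'   `pT_values` (probabilities in \[0, 1\], 0 at t = 0).
#' @examples
#' pr <- propagate_triplet_probability(
#'   radical_pair_system("bare", list()), 50, c(0, 1e-7))
#' pr$pT_values  # identically 0: no hyperfine couplings, no interconversion
#' @export
propagate_triplet_probability <- function(system, B_uT, times) {
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  H <- build_hamiltonian(system, B_uT)
  PS <- singlet_projector(system)
  rho0 <- PS / system$M
  pT <- vapply(times, function(t) {
    U <- .expm_complex(-1i * H * t)
    rho_t <- U %*% rho0 %*% Conj(t(U))
    1 - Re(sum(diag(PS %*% rho_t)))
  }, numeric(1))
  structure(list(times = times, pT_values = pT), class = "propagation_result")
}

#' Triplet yield by time-domain quadrature
#'
#' Evaluates \eqn{\Phi_T = k \int_0^\infty p_T(t) e^{-kt} dt} numerically:
#' the integral is truncated at \eqn{T_{max} = 40/k} (neglected tail below
#' \eqn{e^{-40}}) and computed by adaptive Gauss-Kronrod quadrature on
#' segments short enough to resolve the fastest coherence oscillation.
#' Serves as an independent cross-check of the closed-form
#' [triplet_yield()].
#'
#' @param system A [radical_pair_system()].
#' @param B_uT Static field, uT.
#' @param kin A [reaction_kinetics()].
#' @param rel_tol Relative tolerance of each quadrature segment.
#' @return The yield \eqn{\Phi_T}.
#' @examples
#' sys <- radical_pair_system("one-N", list(nucleus("N", 1, 300, "A")))
#' yield_numeric(sys, 50, reaction_kinetics(k = 1e6, r = 1e6))
#' @export
yield_numeric <- function(system, B_uT, kin, rel_tol = 1e-8) {
  stopifnot(inherits(kin, "reaction_kinetics"))
  spec <- spectral_decomposition(system, B_uT)
  k <- kin$k; r <- kin$r
  t_max <- 40 / k
  # segment so the fastest oscillation is sampled ~4 segments per period
  omega_span <- max(abs(spec$domega))
  n_seg <- if (omega_span > 0) {
    min(4000L, max(8L, ceiling(4 * t_max * omega_span / (2 * pi))))
  } else 8L
  breaks <- seq(0, t_max, length.out = n_seg + 1L)
  integrand <- function(t) {
    k * triplet_probability(spec, t, r) * exp(-k * t)
  }
  total <- 0
  for (i in seq_len(n_seg)) {
    seg <- stats::integrate(integrand, breaks[i], breaks[i + 1L],
                            rel.tol = rel_tol, abs.tol = rel_tol / n_seg,
                            stop.on.error = FALSE)
    if (!seg$message %in% c("OK", "the integral is probably divergent")) {
      cond <- structure(
        class = c("radicalpair_accuracy_error", "error", "condition"),
        list(message = paste("time-domain quadrature failed:", seg$message),
             call = sys.call(-1), estimates = total))
      stop(cond)
    }
    total <- total + seg$value
  }
  total
}
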