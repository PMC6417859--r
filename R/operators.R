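#' Angular momentum operator matrices
#'
#' Builds the standard spin angular momentum matrices Jx, Jy, Jz in the
#' \eqn{|I, m_I\rangle} basis ordered by descending magnetic quantum number
#' \eqn{m_I = I, I-1, \ldots, -I}.  The raising operator matrix elements are
#' \eqn{\langle I, m+1 | J_+ | I, m \rangle = \sqrt{I(I+1) - m(m+1)}}.
#'
#' @param multiplicity Integer 2I + 1 (>= 2).
#' @return A list with complex matrices `x`, `y`, `z`, each Hermitian of size
#'   `multiplicity`.
#' @examples
#' J <- angular_momentum_operators(2)
#' J$z  # diag(1/2, -1/2)
#' @export
angular_momentum_operators <- function(multiplicity) {
  if (!is.numeric(multiplicity) || length(multiplicity) != 1L ||
      multiplicity < 2 || multiplicity != round(multiplicity)) {
    stop("'multiplicity' must be an integer >= 2", call. = FALSE)
  }
  multiplicity <- as.integer(multiplicity)
  I <- (multiplicity - 1) / 2
  m <- seq(I, -I, by = -1)
  Jz <- diag(m) + 0i
  Jp <- matrix(0i, multiplicity, multiplicity)
  for (j in seq_len(multiplicity - 1L)) {
    # column j+1 holds m[j+1]; J+ raises it into row j (m[j] = m[j+1] + 1)
    mm <- m[j + 1L]
    Jp[j, j + 1L] <- sqrt(I * (I + 1) - mm * (mm + 1))
  }
  Jm <- Conj(t(Jp))
  list(x = (Jp + Jm) / 2, y = (Jp - Jm) / 2i, z = Jz)
}

# embed a single-factor operator at position `pos` of the tensor product
# defined by factor multiplicities `dims`
.kron_embed <- function(op, pos, dims) {
  out <- matrix(1 + 0i, 1L, 1L)
  for (i in seq_along(dims)) {
    out <- kronecker(out, if (i == pos) op else diag(dims[i]) + 0i)
  }
  out
}

# scalar coupling op1.op2 between factor positions p1 and p2 (lists of x,y,z)
.dot_coupling <- function(ops1, p1, ops2, p2, dims) {
  acc <- NULL
  for (cmp in c("x", "y", "z")) {
    term <- .kron_embed(ops1[[cmp]], p1, dims) %*%
      .kron_embed(ops2[[cmp]], p2, dims)
    acc <- if (is.null(acc)) term else acc + term
  }
  acc
}

#' Spin Hamiltonian of the radical pair
#'
#' Assembles \deqn{H = \omega (S_{Az} + S_{Bz}) + \sum_n a_n \, S \cdot I_n}
#' in angular frequency units (rad s\eqn{^{-1}}), where \eqn{\omega = \gamma_e
#' B} is the electron Larmor frequency and the sum runs over all nuclei, each
#' coupled to its own electron.  Both radicals carry the free-electron
#' g-value, so their Zeeman terms are identical; anisotropic hyperfine
#' components, nuclear Zeeman terms and electron-electron exchange/dipolar
#' couplings are not part of the model.
#'
#' @param system A [radical_pair_system()].
#' @param B_uT Static magnetic flux density, uT (>= 0).
#' @return A complex Hermitian matrix of size `system$dim`.
#' @examples
#' H <- build_hamiltonian(rp_preset("FAD-Z"), 50)
#' dim(H)  # 36 x 36
#' @export
build_hamiltonian <- function(system, B_uT) {
  stopifnot(inherits(system, "radical_pair"))
  if (!is.numeric(B_uT) || length(B_uT) != 1L || B_uT < 0) {
    stop("'B_uT' must be a non-negative number", call. = FALSE)
  }
  dims <- system$dims
  e_ops <- angular_momentum_operators(2L)
  omega <- .uT_to_rad_s(B_uT)
  H <- omega * (.kron_embed(e_ops$z, 1L, dims) + .kron_embed(e_ops$z, 2L, dims))
  for (n in seq_along(system$nuclei)) {
    nuc <- system$nuclei[[n]]
    a <- .uT_to_rad_s(nuc$coupling_uT)
    epos <- if (nuc$electron == "A") 1L else 2L
    n_ops <- angular_momentum_operators(nuc$multiplicity)
    H <- H + a * .dot_coupling(e_ops, epos, n_ops, 2L + n, dims)
  }
  H
}

#' Singlet projection operator
#'
#' The projector onto the electron singlet subspace,
#' \eqn{P_S = \frac{1}{4}\mathbf{1} - S_A \cdot S_B}, extended over the
#' nuclear spin space.  It is idempotent and its trace equals M, the number
#' of nuclear spin configurations (one singlet level per configuration).
#'
#' @param system A [radical_pair_system()].
#' @return A complex Hermitian idempotent matrix of size `system$dim`.
#' @examples
#' P <- singlet_projector(rp_preset("FAD-Z"))
#' Re(sum(diag(P)))  # 9
#' @export
singlet_projector <- function(system) {
  stopifnot(inherits(system, "radical_pair"))
  dims <- system$dims
  e_ops <- angular_momentum_operators(2L)
  0.25 * diag(system$dim) - .dot_coupling(e_ops, 1L, e_ops, 2L, dims)
}
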