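test_that("angular momentum matrices satisfy the su(2) algebra and Casimir", {
  for (mult in 2:5) {
    J <- angular_momentum_operators(mult)
    I <- (mult - 1) / 2
    # Hermitian
    for (cmp in c("x", "y", "z")) {
      expect_lt(max(Mod(J[[cmp]] - Conj(t(J[[cmp]])))), 1e-12)
    }
    # [Jx, Jy] = i Jz
    comm <- J$x %*% J$y - J$y %*% J$x
    expect_lt(max(Mod(comm - 1i * J$z)), 1e-12)
    # Casimir J^2 = I(I+1) 1
    J2 <- J$x %*% J$x + J$y %*% J$y + J$z %*% J$z
    expect_lt(max(Mod(J2 - I * (I + 1) * diag(mult))), 1e-12)
  }
})

test_that("spin-1/2 Jz is diag(1/2, -1/2) with descending m ordering", {
  J <- angular_momentum_operators(2)
  expect_equal(Re(diag(J$z)), c(0.5, -0.5))
  expect_error(angular_momentum_operators(1), "multiplicity")
})

test_that("nuclei-free Hamiltonian has the pure Zeeman spectrum", {
  H <- build_hamiltonian(bare_system(), 50)
  omega <- physical_constants()$gamma_e * 50e-6
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, sort(c(-omega, 0, 0, omega)), tolerance = 1e-12)
})

test_that("Hamiltonian is Hermitian, traceless, and of the right dimension", {
  for (sys in c(fixture_systems(2), list(rp_preset("FAD-TrpH")))) {
    H <- build_hamiltonian(sys, 37.5)
    expect_equal(nrow(H), sys$dim)
    expect_lt(max(Mod(H - Conj(t(H)))), 1e-12 * max(Mod(H)))
    expect_lt(Mod(sum(diag(H))), 1e-10 * norm(H, "F"))
  }
  expect_equal(rp_preset("FAD-TrpH")$dim, 108L)
  expect_equal(rp_preset("FAD-Z")$dim, 36L)
})

test_that("singlet projector is an idempotent of trace M", {
  for (sys in list(rp_preset("FAD-TrpH"), tiny_system())) {
    P <- singlet_projector(sys)
    expect_lt(max(Mod(P %*% P - P)), 1e-12)
    expect_equal(Re(sum(diag(P))), sys$M, tolerance = 1e-12)
  }
})

test_that("electron singlet x nuclear basis state is a unit eigenvector of the projector", {
  sys <- tiny_system()
  P <- singlet_projector(sys)
  # basis order: electron A x electron B x nucleus, m descending.
  # singlet = (|ud> - |du>)/sqrt(2) on the electron factors
  singlet <- rep(0i, 4)
  singlet[2] <- 1 / sqrt(2)   # |u d>
  singlet[3] <- -1 / sqrt(2)  # |d u>
  for (nuc_state in 1:3) {
    nvec <- rep(0i, 3); nvec[nuc_state] <- 1
    v <- as.vector(kronecker(singlet, nvec))
    expect_lt(max(Mod(P %*% v - v)), 1e-12)
  }
})

test_that("nucleus and system constructors validate their inputs", {
  expect_error(nucleus("x", spin = 0.7, coupling_uT = 10), "half-integer")
  expect_error(nucleus("x", spin = 1, coupling_uT = Inf), "finite")
  expect_error(reaction_kinetics(k = 1e6, tau = 1e-6, r = 0), "exactly one")
  expect_error(reaction_kinetics(k = -1, r = 0), "positive")
  expect_error(reaction_kinetics(k = 1e6, r = -1), "non-negative")
  sys <- radical_pair_system("s", list(nucleus("a", 0.5, 100, "A"),
                                       nucleus("b", 1, 100, "B")))
  expect_equal(sys$dim, 4L * 2L * 3L)
  expect_equal(sys$M, 6L)
})
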