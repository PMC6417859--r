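test_that("projector weights are symmetric, non-negative, and sum to M", {
  for (sys in c(fixture_systems(3), list(rp_preset("FAD-TrpH"),
                                         rp_preset("FAD-Z")))) {
    for (B in c(0, 50, 1234.5)) {
      sp <- spectral_decomposition(sys, B)
      expect_true(all(sp$weights >= 0))
      expect_equal(sp$weights, t(sp$weights), tolerance = 1e-12)
      expect_rel_equal(sum(sp$weights), sys$M, 1e-9)
    }
  }
})

test_that("eigenfrequencies reproduce the Hamiltonian's invariant traces", {
  for (sys in fixture_systems(2)) {
    H <- build_hamiltonian(sys, 50)
    sp <- spectral_decomposition(sys, 50)
    expect_rel_equal(sum(sp$omegas^2), Re(sum(diag(H %*% H))), 1e-9)
    expect_lt(abs(sum(sp$omegas)), 1e-9 * sqrt(sum(sp$omegas^2)))
  }
})

test_that("nuclei-free weights are confined to the zero-frequency block", {
  sp <- spectral_decomposition(bare_system(), 50)
  # P_S commutes with H: all weight sits in the degenerate omega = 0
  # subspace spanned by |ud>, |du> (the eigenbasis within that block is
  # arbitrary), and sums to 1
  expect_rel_equal(sum(sp$weights), 1, 1e-10)
  zero_freq <- abs(sp$omegas) < 1e-3 * max(abs(sp$omegas))
  expect_lt(sum(sp$weights[!zero_freq, ]), 1e-10)
  expect_rel_equal(sum(sp$weights[zero_freq, zero_freq]), 1, 1e-10)
})

test_that("triplet probability starts at zero and relaxes to 3/4", {
  sp <- spectral_decomposition(tiny_system(), 50)
  expect_equal(triplet_probability(sp, 0, r = 1e6), 0, tolerance = 1e-12)
  expect_equal(triplet_probability(sp, 1e-3, r = 1e6), 0.75, tolerance = 1e-9)
  t_grid <- seq(0, 2e-6, length.out = 50)
  p <- triplet_probability(sp, t_grid, r = 1e6)
  expect_true(all(p >= -1e-12 & p <= 1 + 1e-12))
  expect_error(triplet_probability(sp, -1, 0), "non-negative")
})

test_that("coherent triplet probability matches unitary propagation", {
  times <- seq(0, 5e-7, length.out = 50)
  for (sys in c(list(tiny_system()), fixture_systems(2, seed = 7))) {
    if (sys$dim > 36) next  # keep brute-force matrix exponentials cheap
    sp <- spectral_decomposition(sys, 50)
    prop <- propagate_triplet_probability(sys, 50, times)
    expect_equal(triplet_probability(sp, times, r = 0), prop$pT_values,
                 tolerance = 1e-10)
  }
})

test_that("nuclei-free pair never leaves the singlet state", {
  prop <- propagate_triplet_probability(bare_system(), 50,
                                        c(0, 1e-7, 1e-6))
  expect_equal(prop$pT_values, c(0, 0, 0), tolerance = 1e-12)
})

test_that("closed-form yield limits hold", {
  # no hyperfine couplings: Phi_T = (3/4) r/(k+r), independent of field
  for (B in c(0, 50, 5000)) {
    sp <- spectral_decomposition(bare_system(), B)
    expect_rel_equal(triplet_yield(sp, reaction_kinetics(k = 1e6, r = 1e6)),
                     0.375, 1e-12)
    expect_equal(triplet_yield(sp, reaction_kinetics(k = 1e6, r = 0)), 0,
                 tolerance = 1e-12)
  }
  sp50 <- spectral_decomposition(rp_preset("FAD-TrpH"), 50)
  # k -> infinity: the pair reacts before any interconversion
  expect_equal(triplet_yield(sp50, reaction_kinetics(k = 1e12, r = 1e6)), 0,
               tolerance = 1e-3)
  # r -> infinity: statistical 3/4
  expect_equal(triplet_yield(sp50, reaction_kinetics(k = 1e6, r = 1e12)),
               0.75, tolerance = 1e-3)
  # long-lived pair at Earth-strength field sits near 0.75
  expect_equal(triplet_yield(sp50, reaction_kinetics(tau = 1e-4, r = 1e6)),
               0.75, tolerance = 0.01)
})

test_that("spectral yield equals time-domain quadrature on random fixtures", {
  for (sys in c(list(tiny_system()), fixture_systems(2, seed = 11))) {
    if (sys$dim > 36) next  # quadrature cost grows with the coherence count
    sp <- spectral_decomposition(sys, 50)
    for (kin in list(reaction_kinetics(k = 1e6, r = 0),
                     reaction_kinetics(k = 2e6, r = 1e6))) {
      expect_rel_equal(triplet_yield(sp, kin),
                       yield_numeric(sys, 50, kin), 1e-6)
    }
  }
})
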