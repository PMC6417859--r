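kin_1us <- reaction_kinetics(tau = 1e-6, r = 1e6)

test_that("the static-field response is biphasic at tau = 1 us (low field effect)", {
  sw <- phi_vs_field(rp_preset("FAD-TrpH"), kin_1us, c(0, 500, 5000))
  expect_gt(sw$values[2], sw$values[1])  # LFE bump below 1 mT
  expect_lt(sw$values[3], sw$values[1])  # larger decrease by 5 mT
})

test_that("long-lived pairs are almost field-independent", {
  kin <- reaction_kinetics(tau = 1e-4, r = 1e6)
  sw <- phi_vs_field(rp_preset("FAD-TrpH"), kin,
                     seq(0, 5000, length.out = 11))
  expect_lt(max(sw$values) - min(sw$values), 0.01)
  expect_error(phi_vs_field(rp_preset("FAD-TrpH"), kin, numeric(0)), "empty")
})

test_that("yield derivatives vanish without hyperfine couplings", {
  sys <- bare_system()
  expect_lt(abs(phi_derivative(sys, kin_1us, 50, order = 1)), 1e-12)
  expect_lt(abs(phi_derivative(sys, kin_1us, 50, order = 2)), 1e-10)
})

test_that("the yield gradient at 50 uT is positive for tau = 1 us", {
  expect_gt(phi_derivative(rp_preset("FAD-TrpH"), kin_1us, 50, order = 1), 0)
})

test_that("derivatives match an independent local quadratic fit", {
  sys <- rp_preset("FAD-Z")
  x <- c(-0.2, -0.1, 0, 0.1, 0.2)
  phi <- phi_vs_field(sys, kin_1us, 50 + x)$values
  fit <- stats::lm(phi ~ x + I(x^2))
  slope <- unname(stats::coef(fit)[2])
  curv <- 2 * unname(stats::coef(fit)[3])
  expect_rel_equal(phi_derivative(sys, kin_1us, 50, order = 1), slope, 1e-2)
  expect_rel_equal(phi_derivative(sys, kin_1us, 50, order = 2), curv, 1e-2)
})

test_that("ELF effect vanishes exactly at zero amplitude", {
  proto0 <- field_protocol(50, 0)
  expect_identical(mfe_elf_taylor(rp_preset("FAD-Z"), kin_1us, proto0)$value, 0)
  expect_identical(
    mfe_elf_quadrature(rp_preset("FAD-Z"), kin_1us, proto0)$value, 0)
  expect_identical(
    mfe_gmf(rp_preset("FAD-Z"), kin_1us, field_protocol(50, 1, 0))$value, 0)
})

test_that("Taylor estimate enforces its validity bound", {
  expect_error(mfe_elf_taylor(rp_preset("FAD-Z"), kin_1us,
                              field_protocol(50, 15)), "0.2")
  expect_error(mfe_gmf(rp_preset("FAD-Z"), kin_1us,
                       field_protocol(50, 1, -15), method = "linear"), "0.2")
})

test_that("Taylor and phase-average quadrature agree at B1/B0 = 0.02", {
  sys <- rp_preset("FAD-TrpH")
  cache <- radicalpair:::.spectral_cache(sys)
  proto <- field_protocol(50, 1)
  for (tau in 10^seq(-7.5, -5.5, length.out = 5)) {
    kin <- reaction_kinetics(tau = tau, r = 1e6)
    mt <- mfe_elf_taylor(sys, kin, proto, cache = cache)$value
    mq <- mfe_elf_quadrature(sys, kin, proto, cache = cache)$value
    expect_rel_equal(mt, mq, 0.05)
  }
})

test_that("the ELF effect is quadratic in B1 and the GMF effect linear in dB0", {
  sys <- rp_preset("FAD-Z")
  cache <- radicalpair:::.spectral_cache(sys)
  kin <- reaction_kinetics(tau = 3e-7, r = 1e6)
  m1 <- mfe_elf_quadrature(sys, kin, field_protocol(50, 1), cache = cache)$value
  m2 <- mfe_elf_quadrature(sys, kin, field_protocol(50, 2), cache = cache)$value
  expect_rel_equal(m2 / m1, 4, 0.05)
  g1 <- mfe_gmf(sys, kin, field_protocol(50, 1, -0.05), cache = cache)$value
  g2 <- mfe_gmf(sys, kin, field_protocol(50, 1, -0.1), cache = cache)$value
  expect_rel_equal(g2 / g1, 2, 0.02)
})

test_that("exact-difference and linearised GMF effects agree for small offsets", {
  sys <- rp_preset("FAD-TrpH")
  cache <- radicalpair:::.spectral_cache(sys)
  for (dB0 in c(-0.1, 0.05)) {
    proto <- field_protocol(50, 1, dB0)
    ex <- mfe_gmf(sys, kin_1us, proto, "exact_difference", cache = cache)$value
    li <- mfe_gmf(sys, kin_1us, proto, "linear", cache = cache)$value
    expect_rel_equal(ex, li, 0.02)
  }
})

test_that("a coupling-free system yields a degenerate (flat) extremum", {
  expect_warning(
    ext <- lifetime_extremum(bare_system(), 1e6, field_protocol(50, 1), "elf",
                             tau_range = c(1e-8, 1e-5),
                             points_per_decade = 5),
    "flat")
  expect_true(ext$degenerate)
  expect_true(is.na(ext$tau_star))
})

test_that("the mfe ratio scales as 1/B1^2 at fixed dB0", {
  sys <- rp_preset("FAD-Z")
  cache <- radicalpair:::.spectral_cache(sys)
  om1 <- omega_ratio(sys, 1e6, B1_uT = 1, cache = cache)$omega
  om2 <- omega_ratio(sys, 1e6, B1_uT = 2, cache = cache)$omega
  expect_rel_equal(om2 / om1, 0.25, 0.05)
})

test_that("equivalent static change is -B1 * 1000 / Omega nT", {
  expect_equal(equivalent_static_change(1000, 1), -1)
  expect_error(equivalent_static_change(0, 1), "nonzero")
})

test_that("mfe_vs_lifetime returns a ppm sweep consistent with pointwise calls", {
  sys <- rp_preset("FAD-Z")
  taus <- 10^seq(-7, -6, length.out = 3)
  sw <- mfe_vs_lifetime(sys, 1e6, field_protocol(50, 1), taus, "elf")
  expect_equal(sw$axis_values, taus)
  one <- mfe_elf_taylor(sys, reaction_kinetics(tau = taus[2], r = 1e6),
                        field_protocol(50, 1))
  expect_rel_equal(sw$values[2], one$ppm, 1e-6)
  expect_equal(one$ppm, one$value * 1e6)
})
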