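# Shared fixtures: small random spin systems for property tests.
# Seeded here so every test file sees the same draws.

fixture_systems <- function(n = 3L, seed = 42L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) random_radical_pair()))
}

# a one-nucleus system small enough for brute-force propagation
tiny_system <- function() {
  radical_pair_system("one-N", list(nucleus("N", 1, 300, "A")))
}

bare_system <- function() {
  radical_pair_system("bare", list())
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
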