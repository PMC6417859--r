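Package: radicalpair
Title: Radical-Pair Spin Dynamics and Weak Magnetic Field Effects
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the coherent spin dynamics of singlet-born radical
    pairs with isotropic hyperfine couplings and computes spin-selective
    reaction yields under static and extremely-low-frequency (ELF, 50/60 Hz)
    magnetic fields.  The triplet yield is obtained from the spectral
    decomposition of the spin Hamiltonian with phenomenological exponential
    spin relaxation.  Includes field and lifetime sweeps, Taylor-series and
    phase-average estimates of ELF field effects, geomagnetic sensitivity,
    temperature (rate constant) sensitivity, and brute-force propagation
    oracles for validation.  Bundles cryptochrome-like flavin-tryptophan
    radical pair presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    pracma,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
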