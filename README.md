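# radicalpair

Spin-dynamics simulation of **radical pair magnetic field effects**: how weak
static and extremely-low-frequency (ELF, 50/60 Hz) magnetic fields, and small
temperature-driven rate changes, alter the yield of a spin-selective radical
pair reaction.

The package is aimed at spin chemists and quantitative biologists who want
reproducible, desk-scale estimates of weak-field sensitivities for
cryptochrome-like radical pairs — for example to put the ~1 uT ELF exposures
discussed in the bioelectromagnetics literature on the same footing as
everyday variations in the geomagnetic field and in body temperature.

## The model

A singlet-born pair of radicals (electrons A and B) evolves under the spin
Hamiltonian with isotropic hyperfine couplings *a*ₙ (in field units) and a
Zeeman term at the free-electron g-value:

    H = γe·B·(S_Az + S_Bz) + Σₙ aₙ S·Iₙ

Both reaction channels share one rate constant *k* (lifetime τ = 1/*k*), and
spin relaxation drives the pair exponentially (rate *r*) towards the
statistical 1:3 singlet:triplet mixture.  The ultimate triplet yield Φ_T
follows in closed form from the eigendecomposition of H:

    Φ_T = 3/4 + k/[4(k+r)] − (1/M) Σ_mn |⟨m|P_S|n⟩|² · k(k+r)/[(k+r)² + (ω_m−ω_n)²]

Field sensitivities are quantified as fractional yield changes:
`mfe_elf_taylor()` (∝ B₁²·Φ_T″/Φ_T, the curvature measure for an ELF field of
peak amplitude B₁), `mfe_gmf()` (∝ ΔB₀·Φ_T′/Φ_T for a static offset),
`temperature_effect()` (rate-constant perturbations), each extremised over
lifetimes with `lifetime_extremum()`.  Two presets are bundled: the
three-nitrogen flavin/tryptophan pair (`"FAD-TrpH"`, Hilbert dimension 108)
and the coupling-asymmetric `"FAD-Z"` variant (dimension 36).

## Worked example

```r
library(radicalpair)
trph <- rp_preset("FAD-TrpH")
trph
#> <radical_pair> FAD-TrpH
#>   electrons: 2 (A, B), singlet-born; nuclei: 3
#>     N5   I = 1, a = 523 uT, electron A
#>     N10  I = 1, a = 189 uT, electron A
#>     N1   I = 1, a = 322 uT, electron B
#>   Hilbert dimension 108, nuclear configurations M = 27

# yield at Earth-strength field, 1 us lifetime, 1 us coherence time
kin <- reaction_kinetics(tau = 1e-6, r = 1e6)
triplet_yield(spectral_decomposition(trph, 50), kin)
#> [1] 0.709339

# largest ELF effect (1 uT peak, parallel to a 50 uT static field)
# over lifetimes 1 ns - 1 ms:
lifetime_extremum(trph, r = 1e6, field_protocol(B0_uT = 50, B1_uT = 1), "elf")
#> <lifetime_extremum> elf: -1.2 ppm at tau* = 5.39e-07 s

run_table1()
#>       quantity            conditions FAD-TrpH FAD-Z
#>  mfeELFmax_ppm             B1 = 1 uT     -1.2   -14
#>  mfeGMFmax_ppm           dB0 = -1 uT   -330.0 -2100
#>          Omega mfeGMFmax / mfeELFmax    280.0   150
#>      Te_dk_ppm          dk = 1000 /s    -36.0   -54
#>      Te_dr_ppm          dr = 1000 /s     21.0    27
#>   Te_dk_dr_ppm     dk = dr = 1000 /s    -15.0   -27
```

Reading the table: a 1 uT ELF field changes the reaction yield of the
flavin/tryptophan model by at most ≈ 1 part per million (14 ppm for the
maximally sensitive coupling-free partner), two orders of magnitude less
than a 1 uT *static* field change under identical conditions (the Omega
row), and no larger than the yield changes produced by 0.1% shifts in the
reaction/relaxation rates — the scale expected from a ±0.5 °C body
temperature swing.  Equivalently, `equivalent_static_change(280, 1)` ≈ −3.6
nT: the ELF exposure is worth a few nanotesla of static field, the amount
the geomagnetic field changes over a kilometre of north–south travel
(`geomagnetic_distance_equivalent()`).

`run_figure_data("fig2" | "fig4" | ...)` writes the underlying field and
lifetime sweep curves as annotated CSV/JSON, and
`inst/scripts/radicalpair-cli.R` exposes `table1`, `fig`, `mfe` and
`context` subcommands for shell use.

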