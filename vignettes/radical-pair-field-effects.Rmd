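---
title: "Modelling weak magnetic field effects on radical pair reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling weak magnetic field effects on radical pair reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radicalpair)
```

## The model

Radical pairs are short-lived reaction intermediates carrying two correlated
unpaired electron spins.  Born in an electron singlet state (as after
photo-induced electron transfer in cryptochrome, the motivating system for
the bundled presets), a pair coherently interconverts with its triplet state
under the internal hyperfine interactions and the Zeeman interaction with any
external magnetic field.  Because singlet and triplet pairs react through
different channels, this interconversion makes reaction yields sensitive to
magnetic interactions a million times smaller than the thermal energy.

The spin system comprises the two electrons (one per radical, labelled A and
B) and a small set of nuclear spins, each coupled isotropically to its
electron.  The Hamiltonian, in angular frequency units, is

$$\hat H = \omega\,(\hat S_{Az} + \hat S_{Bz}) + \sum_n a_n\, \hat S \cdot \hat I_n,
\qquad \omega = \gamma_e B,$$

with both radicals assigned the free-electron g-value 2.0023 (the difference
in their Zeeman interactions is negligible at the field strengths of
interest).  Couplings and fields are stored in microtesla and converted to
rad s⁻¹ through $\gamma_e = g_e \mu_B/\hbar$ at a single point
(`physical_constants()`), which prevents unit drift.  Anisotropic hyperfine
components (relevant only for immobilised, aligned radicals),
electron–electron exchange and dipolar couplings, and nuclear Zeeman terms
are all outside the model.

With eigenstates $|m\rangle$ and eigenfrequencies $\omega_m$ of $\hat H$, the
probability that a singlet-born pair is triplet at time $t$, before
relaxation, is

$$p_T'(t) = 1 - \frac{1}{M}\sum_{m,n} |\langle m|\hat P_S|n\rangle|^2
\cos[(\omega_m - \omega_n)t],$$

where $\hat P_S = \tfrac14 \mathbf{1} - \hat S_A\cdot\hat S_B$ is the singlet
projector and $M$ the number of nuclear spin configurations.  Spin relaxation
is phenomenological — exponential decay at rate $r$ towards the statistical
1:3 singlet:triplet mixture:

$$p_T(t) = \tfrac34 + \left(p_T'(t) - \tfrac34\right)e^{-rt}.$$

Both reaction channels share one rate constant $k$ (the "exponential model"),
so the ultimate triplet yield $\Phi_T = k\int_0^\infty p_T(t)e^{-kt}\,dt$ has
the closed form

$$\Phi_T = \frac34 + \frac{k}{4(k+r)} - \frac{1}{M}\sum_{m,n}
|\langle m|\hat P_S|n\rangle|^2 \frac{k(k+r)}{(k+r)^2 + (\omega_m-\omega_n)^2}.$$

`spectral_decomposition()` computes $\omega_m$ and the weight matrix once per
(system, field); `triplet_yield()` is then a cheap Lorentzian sum, so sweeps
over lifetimes reuse one decomposition.  This caching is the main performance
lever: a full lifetime extremisation costs only a handful of 108×108 complex
Hermitian eigendecompositions.

## Field-effect measures

A 50/60 Hz (ELF) field of peak amplitude $B_1$ parallel to the static field
$B_0$ is effectively static over a microsecond pair lifetime; each pair sees
the total field $B_0 + B_1\cos\alpha$ with the phase $\alpha$ uniform on
$(0,\pi)$ across the ensemble.  The ELF effect is the fractional change of
the phase-averaged yield,

$$\mathrm{mfe}_{ELF} = \frac{\overline{\Phi_T} - \Phi_T(B_0)}{\Phi_T(B_0)}
\approx \frac14 B_1^2\, \frac{\Phi_T''(B_0)}{\Phi_T(B_0)},$$

quadratic in $B_1$ and proportional to the *curvature* of the yield curve
(`mfe_elf_taylor()`; `mfe_elf_quadrature()` evaluates the phase average
directly).  The analogous geomagnetic measure for a static offset
$\Delta B_0$ is linear in the offset and proportional to the *gradient*:
$\mathrm{mfe}_{GMF} \approx \Delta B_0\, \Phi_T'(B_0)/\Phi_T(B_0)$
(`mfe_gmf()`).  Temperature sensitivity enters through the rate constants:
`temperature_effect()` evaluates the fractional yield change under increments
$\Delta k$, $\Delta r$.

```{r example}
fadz <- rp_preset("FAD-Z")
kin <- reaction_kinetics(tau = 1e-6, r = 1e6)
mfe_elf_taylor(fadz, kin, field_protocol(B0_uT = 50, B1_uT = 1))
```

## Default parameters and why

* **B0 = 50 uT** — a typical mid-latitude geomagnetic strength; the Earth's
  field spans roughly 25 uT (magnetic equator) to 65 uT (poles), and
  `run_figure_data("fig4s3")` regenerates the sensitivity at those extremes.
* **B1 = 1 uT** — the peak amplitude corresponding to the ~0.7 uT rms
  chronic ELF exposures discussed in the childhood-leukaemia epidemiology
  (0.7 × √2 ≈ 1).  Parallel alignment with B0 is the worst case; random
  orientation reduces the effective amplitude by ~0.64
  (`randomly_oriented_effective_field_range()`).
* **dB0 = −1 uT** — matched in magnitude to B1 and negative so the two
  measures have (mostly) the same sign, making their ratio Ω meaningful.
* **r = 1e6 s⁻¹** (coherence time 1 us) — a generous estimate for organic
  radicals at physiological temperature; faster relaxation shrinks every
  field effect.  The 1e5 and 1e7 s⁻¹ variants quantify that dependence.
* **τ ∈ [1 ns, 1 ms]** — the extremisation range for lifetimes; field
  effects need lifetimes comparable to the ~700 ns Larmor period at 50 uT,
  so the range brackets the sensitive window by decades on both sides.
* **Hyperfine presets** — the three nitrogens with the largest isotropic
  couplings of the flavin/tryptophan pair (523, 189, 322 uT, DFT values);
  the FAD-Z preset removes all couplings from the partner radical, the
  coupling asymmetry that maximises low-field sensitivity.
* **0.1% per °C rate changes** (`arrhenius_activation_energy()`) — a small
  activation energy (~0.8 kJ/mol at 310.15 K, i.e. ~0.31 RT); 37 °C is
  interpreted as 310.15 K.  The figure is a parameter, not a constant, so
  sensitivity scans are possible.

## Numerical choices

* **Eigendecomposition** treats $\hat H$ as complex Hermitian
  (`eigen(symmetric = TRUE)`); at dimension ≤ 108 there is no case for a
  real-symmetric transformation.  Degenerate eigenvalues need no special
  handling — the yield formula is smooth at $\Delta\omega = 0$ — but tests
  of the weight matrix must not assume the eigenbasis diagonalises $P_S$
  within a degenerate block (it need not).
* **Yield derivatives** use Richardson-extrapolated central differences,
  base step h = 0.05 uT with step-halving; `phi_derivative()` reports a
  value only when the two finest extrapolants agree to 1e-3 relative,
  signalling a typed error carrying both estimates otherwise.  Grid scans
  inside `lifetime_extremum()` use the unguarded two-level estimate — far
  from the extremum the response can sit at the noise floor where relative
  agreement is meaningless — and the guarded derivative is applied at the
  refined extremum, where the signal is orders of magnitude above the
  floor.  An analytic perturbation-theory derivative was considered and
  rejected as over-engineering at this matrix size.
* **Phase averaging** uses Gauss–Legendre quadrature on $(0,\pi)$, 20 nodes
  doubled until the mfe changes by less than 1e-4 relative.  Taylor-based
  estimators enforce $B_1 \le 0.2\,B_0$ (and likewise for $|\Delta B_0|$);
  outside that bound only the quadrature path is meaningful.
* **Extremisation** scans a log-spaced lifetime grid (25 points/decade),
  then refines the largest |mfe| by golden-section search to 1e-3 relative
  in τ.  ELF and GMF extrema are located independently; their optimal
  lifetimes differ.  A flat response (couplings all zero) is flagged
  degenerate rather than returning a spurious extremum.
* **Oracles**: `propagate_triplet_probability()` re-derives $p_T'(t)$ by
  matrix exponentials of the full Hamiltonian acting on the density operator
  $P_S/M$ (the uniform nuclear ensemble), with no eigenbasis shortcuts;
  `yield_numeric()` integrates $k\,p_T(t)e^{-kt}$ by adaptive quadrature on
  segments short enough to resolve the fastest coherence, truncating at
  $40/k$ (tail below $e^{-40}$).  The test suite requires the spectral route
  to agree with both to 1e-10 (probabilities) and 1e-6 relative (yields).
* **Reported precision**: print methods round mfe values to 2 significant
  figures, the scale at which such estimates are meaningful; result objects
  keep full precision.

## What the random fixtures do and do not show

Property tests draw small random systems (1–3 nuclei, spin 1/2 or 1,
couplings uniform on 50–600 uT) and check the invariants that must hold for
*every* system: weight-sum conservation ($\sum_{mn} w_{mn} = M$), kinetic
limits ($\Phi_T \to 0$ as $k\to\infty$, $\to 3/4$ as $r\to\infty$, the
coupling-free closed form $\tfrac34 r/(k+r)$), field-independence without
couplings, and agreement with the brute-force oracles.  Passing these shows
the spin algebra and yield formulas are implemented correctly.  It does not
show that real cryptochrome radical pairs behave like the presets: real
radicals carry many more (and anisotropic) hyperfine couplings, exchange and
dipolar interactions, asymmetric recombination and faster relaxation — all
of which the surrounding literature argues tend to *reduce* weak-field
sensitivity, which is why results from this deliberately favourable model
are read as upper bounds.

## Problem sizes

The shipped analyses use the 108-dimensional three-nitrogen preset and the
36-dimensional two-nitrogen preset; a lifetime extremisation needs ~10
eigendecompositions and runs in well under a second, and the full summary
table (`run_table1()`) in a few seconds.  Figure-data generation
(`run_figure_data()`) at default grid density (25 points/decade in τ, 201
field points) is the largest bundled computation, dominated by one
eigendecomposition per distinct field value.

## Known limitations

* The ELF field is treated as static per pair (quasi-static approximation);
  the time-dependent 50/60 Hz Hamiltonian is never propagated, so genuinely
  dynamic effects (resonances) are out of scope — at ELF frequencies they
  are precluded by relaxation in any case.
* Only singlet-born pairs with symmetric spin-selective recombination are
  modelled; triplet-born and F-pair initial states and asymmetric rate
  schemes are not implemented.
* Relaxation is a single exponential towards 1:3; no microscopic relaxation
  mechanism or temperature dependence is modelled (temperature enters only
  through the rate perturbations).
* The orientation-averaging helper offers two conventions (mean projection
  2/π for an angle uniform on (0, π/2); 1/2 under solid-angle weighting);
  the former is the default because it reproduces the conventional
  49.36–50.64 uT effective window for 1 uT about 50 uT, but the choice is a
  convention, not physics, and both are reported.
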