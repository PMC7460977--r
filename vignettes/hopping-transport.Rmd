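---
title: "Marcus hopping transport in molecular crystals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marcus hopping transport in molecular crystals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopcrystal)
```

## The model

`hopcrystal` treats charge transport in a molecular crystal as a Markovian
sequence of single-carrier hops between neighboring molecules. This is the
appropriate picture when the electronic coupling between neighbors is small
compared to the energy scale of the nuclear relaxation that accompanies
charging, so the carrier localizes on one molecule between hops. Three
assumptions follow and delimit everything below:

* hops are nonadiabatic and thermally activated, so the rate for one
  channel is the semiclassical Marcus expression
  `k = (2π/ħ) J² (4πλk_BT)^(-1/2) exp(-(ΔE-λ)²/(4λk_BT))`;
* successive hops are uncorrelated, so the diffusion tensor of the walk is
  determined exactly by the single-hop rates and geometry;
* the lattice is rigid and periodic: rates depend on the dimer class, not
  on time or position (no energetic disorder, no polaronic band effects,
  no field dependence).

With `ΔE` defined as `E_initial − E_final`, the forward/backward ratio is
`exp(ΔE/k_BT)` (detailed balance) and the rate peaks at `ΔE = λ`, the
inverted-region turnover. For identical molecules in a crystal `ΔE = 0`,
which is the regime of every quantity this package reports by default; the
sign convention only matters if you feed heterodimer site energies.

## Transfer integrals (DIPRO)

`dipro_coupling()` embeds the frontier orbital of each monomer into the
dimer basis (zeros on the partner block), projects the dimer Fock and
overlap matrices onto this two-state space, and removes the overlap by the
symmetric (Löwdin) two-state transformation:

```
e_a = <φ_A|F|φ_A>,  e_b = <φ_B|F|φ_B>,
J_raw = <φ_A|F|φ_B>,  s_ab = <φ_A|S|φ_B>,
J_eff = (J_raw − s_ab (e_a + e_b)/2) / (1 − s_ab²).
```

Downstream transport uses `|J_eff|` (the rate depends on `J²`); the signed
value stays in the object for diagnostics. The site-energy difference
`e_a − e_b` from the same projection is exposed as the `ΔE` input of the
rate.

The classic cross-check, half the splitting of the two dimer levels
dominated by the frontier pair (`splitting_in_dimer()`), is exact only for
equivalent sites: for inequivalent sites the gap is
`sqrt(Δe² + 4J²) > 2|J|`, which is why DIPRO is the default and the
splitting path is kept as an oracle. The assignment of dimer levels to the
frontier pair requires a summed projection weight of at least 0.6 and
errors out otherwise rather than guessing.

Degenerate frontier orbitals (within 10 meV, the `degeneracy_tol`) trigger
a warning and an additional root-mean-square coupling over the degenerate
block (`J_rms`); the scalar frontier-pair value remains the reported one,
because per-direction scalar `J` is what crystal transport summaries use
and the molecules this workflow targets are non-degenerate (benzene-like
toys are the exception, and the warning makes them loud).

## Reorganization energy

`lambda_four_point()` implements the adiabatic-potential ("four-point")
scheme: `λ = (E_N* − E_N) + (E_C* − E_C)`, the sum of the neutral-surface
and charged-surface relaxation energies. Only the inner-sphere
(intramolecular) part is treated; outer-sphere polarization of the
surrounding lattice is not modeled. Each geometry must be the optimum of
its own state; components below `−1e-6 eV` are rejected as inconsistent
input rather than clamped.

`normal_mode_decomposition()` projects the mass-weighted displacement
between the two relaxed geometries onto a normal-mode set:
`Δq_i = L_i · M^(1/2) (x_C − x_N)`, `λ_i = ½ ω_i² Δq_i²`,
`S_i = λ_i / (ħω_i)`. Numerical choices:

* **Eckart alignment** (mass-weighted centroid removal plus a weighted
  Kabsch rotation) is applied to both geometries before projection.
  Without it, `λ_i` would depend on the arbitrary frame of the two input
  geometries; with it, the decomposition is invariant under rigid motion
  of either geometry (tested with random rotations). `align = FALSE` is
  available for pre-aligned input and then an Eckart residual above
  `1e-6 amu^(1/2)·Å` is an error, not a silent acceptance.
* **Modes from one state.** The decomposition uses a single mode set
  (conventionally the neutral-state Hessian). Which state's modes to use,
  and how the two surfaces' curvatures differ, is a genuine modeling
  choice; this package adopts the equal-curvature convention throughout:
  the two four-point components are taken as `λ/2` each, and `λ_i` counts
  each mode once, so `Σλ_i` equals the four-point total identically on
  harmonic input. Mode-resolved tables produced under a different
  single-surface convention can differ by a global factor of 2; compare
  conventions, not just numbers, when matching external results.
* **Units.** Frequencies are cm⁻¹ at the surface, displacements
  amu^(1/2)·Å, energies eV; the conversion constant is fixed by CODATA
  values and audited by the identity that a mode at 1000 cm⁻¹ with
  `S_i = 1` carries `λ_i = ħω ≈ 124 meV`.

`raman_proxy_report()` compares `λ_i` against Raman intensities through the
empirical proxy `I_i/ω_i`: it matches lines to modes by nearest frequency
within a 10 cm⁻¹ window (each line used once, unmatched entries reported,
never dropped), tabulates the pairs and reports their Spearman rank
correlation and the spectrally integrated proxy. It is deliberately
descriptive — a screening aid, not a causal model.

## From rates to mobility

`hopping_diffusion()` assembles `D` from the hop channels around one
central molecule; a dimer class with multiplicity `m` contributes `m`
equivalent channels. Two conventions are implemented and always named in
the report:

* **`msd` (default)** — `D = ½ Σᵢ mᵢ kᵢ (rᵢ ⊗ rᵢ)`, the exact
  mean-square-displacement tensor of the Markov walk. This is the
  convention validated against the kinetic Monte Carlo oracle; its
  isotropic part is `tr(D)/3`.
* **`rate-weighted`** — the literature-common isotropic formula
  `D = (1/6) Σᵢ mᵢ rᵢ² kᵢ Pᵢ` with `Pᵢ = kᵢ/Σⱼ mⱼ kⱼ`. On a cubic
  6-neighbor lattice it evaluates to `k·r²/6` where the MSD convention
  gives the exact `k·r²`; for a single dominant channel the two differ by
  at most a factor ~2. Published hopping-mobility values use both, which
  is why the option exists and why reports are self-labeling.

Mobility is `μ = D_iso/(k_BT/e)` with the thermal voltage in volts
(25.85 mV at the default 300 K). For crystals with several molecules per
cell, all cell molecules serve as centrals and class multiplicities are
averaged over them (uniform weights).

The kinetic Monte Carlo oracle (`simulate_random_walk()`) is a
residence-time walk with exponential waiting times at the total escape
rate. Each trajectory's `D` is estimated by zero-intercept regression of
displacement products over the second half of the trajectory — discarding
the first half guards against transients; for these Markovian walks it is
statistically neutral and kept for methodological hygiene — and
trajectories give the mean and standard error. Validation uses 50 random
planted networks at 200 trajectories × 2000 hops each, the size at which
the standard error is a few percent of `D` and the whole comparison runs
in well under a minute.

## Crystal model

CIF input covers the core-dictionary subset a molecular-crystal workflow
needs: cell parameters, symmetry operation strings (P1 assumed when
absent) and fractional sites. Coordinates are converted once to Cartesian
Å in the standard crystallographic frame (a along x, b in the xy-plane);
everything downstream is Cartesian. Sites with occupancy below 1 are
rejected by default — the crystals this analysis targets are ordered, and
silently picking a disorder component would bias every later stage; a flag
keeps the majority component when that is what you want.

Molecules are connected components under the covalent criterion
`d ≤ r_cov(A) + r_cov(B) + 0.4 Å` (Cordero radii), followed across
periodic boundaries so molecules wrapped over the cell edge are
reassembled into contiguous geometry. A component that reaches an atom
through two different lattice offsets is an infinite covalent network and
is rejected: this is a molecular-crystal tool.

Dimers are enumerated around each cell molecule over a supercell grown
automatically from the perpendicular cell heights so the cutoff sphere is
always covered (at least 3×3×3). The default centroid cutoff of 10 Å
covers every nearest-neighbor shell of acene-sized crystals while keeping
the channel list short; it is a neighborhood definition for transport, not
a physical constant, and is configurable. Symmetry-equivalent pairs are
grouped by a fingerprint — the sorted, element-labeled list of
intermolecular heavy-atom distances rounded to 1e-3 Å — which is invariant
under swapping the two molecules and under rigid motions; ties in
representative choice are broken deterministically by smallest `r`.

## Contact classification

`contact_fractions()` counts reciprocal atom pairs within
`r_vdW(A) + r_vdW(B) + 0.2 Å` (Bondi radii) between a central molecule and
its periodic surroundings, splitting them into conductive (C⋯C, C⋯N,
N⋯N) and insulating (any pair involving H) types. This is a
distance-based proxy, not a molecular-surface partition: absolute
fractions will differ from surface-area-based contact analyses, and the
meaningful output is the trend across related crystals (for instance, the
rise of the conductive fraction along an N-substitution series). The
report header says so.

## The electronic backends

The **tight-binding toy backend** gives every heavy atom (C, N) one
π-type basis function: on-site energies `α_C = −6.55 eV`,
`α_N = −8.55 eV`, intramolecular hopping `β = −2.7 eV`, and an
intermolecular hopping `t(d) = t0·e^(−η(d−d0))` with `t0 = −0.3 eV`,
`η = 1 Å⁻¹`, `d0 = 3.5 Å`, cut off at 6 Å. These magnitudes are
literature-typical for π systems — they put frontier gaps at a few eV and
stacking couplings in the tens-to-hundred meV range — and they are
fixtures of the toy model, chosen once; nothing in the package fits them.
The backend's purpose is to make every pipeline stage exercisable with
exact, fast, deterministic inputs. The overlap is the identity by default
(orthogonal tight binding); an exponential intermolecular overlap block is
available to exercise the overlap-corrected DIPRO path.

The **adapter** ingests externally computed results from a plain-text
format (`#kind fock|overlap|coeffs|energies|hessian|fourpoint|masses`,
`#dim`, `#blocks`, `#nelec` headers; ≥15 significant digits). All type
invariants — Fock symmetry within 1e-10, positive-definite overlap,
`C'SC = I` within 1e-8, ascending energies, `E_N* ≥ E_N`, `E_C* ≥ E_C` —
are enforced at load time, so malformed input fails at the boundary with
the offending matrix named rather than deep inside a calculation.

## What the synthetic generators emulate — and what they do not

`make_stack_crystal()` produces idealized acene-like molecules (fused
hexagons, 1.40 Å bonds, optional centro-symmetric aza substitution) in
face-to-face stacks with configurable spacing and long-axis slip, or a
two-molecule herringbone variant with alternating tilt. The default
non-stacking padding of 1.2 Å puts peripheral hydrogens of adjacent
columns at ~2.4 Å — van der Waals contact, as in a real close-packed
crystal — so side channels and H-mediated contacts exist. The generator
covers the packing-motif phenomenology (stack vs. herringbone classes,
slip-enlarged hop distances, substitution trends); it does not emulate
real cell parameters, thermal motion, disorder, or polymorphism, so a
passing test demonstrates correctness of the machinery, not accuracy for
any particular real crystal.

`make_displaced_harmonic()` plants a known reorganization energy: random
non-planar reference geometry, orthonormal rigid-body-free mode vectors,
displacement `Δ_i` along each mode, `λ_true = Σ ½k_iΔ_i²`, four-point
energies carrying `λ_true/2` per component (the equal-curvature convention
above). Everything is exactly recoverable, which is what makes the 1e-8
and 1e-12 identities in the tests meaningful.

`planted_chain() / planted_cubic() / planted_anisotropic() /
planted_random()` provide hop networks with closed-form or
oracle-checkable diffusion: the anisotropic network (strong stack channel
plus ~20 meV side channels) reproduces the quasi-one-dimensional transport
regime characteristic of well-stacked crystals.

## Degenerate and edge inputs

Empty hop lists return `D = 0` with a warning (not an error: an isolated
molecule is a legitimate query). All-zero rates are an error in the KMC
oracle, which cannot advance time. Mixed temperatures in one hop list are
an input error. Zero HOMO–LUMO gaps warn. Atom pairs closer than 0.5 Å in
a dimer are a geometry error. Pipeline stages run under a wrapper that
names the failing stage.

## Known limitations

* Marcus rates underestimate mobilities of the best crystals, where
  transport is partly band-like or transient-localization limited; this
  package makes no attempt to correct for that.
* No energetic disorder, traps, Coulomb interactions or field dependence;
  the KMC oracle inherits the same idealization (site-independent rates).
* The contact classifier is a pair-count proxy, not a surface partition.
* The tight-binding backend is qualitative by construction; quantitative
  `J` and `λ` require ab initio matrices through the adapter.
* Space-group inference, disorder modeling and open-shell systems are out
  of scope.
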