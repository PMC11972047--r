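---
title: "Methods: gadolinium 43 keV emission as a dose surrogate in scanned proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gadolinium 43 keV emission as a dose surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gadodose)
```

This vignette documents the physics model, the default parameters and their
rationale, the problem sizes, and the known limits of the surrogate engine.
It is a methods reference, not a tutorial; see the README for a worked
example.

## 1. Geometry and materials

The phantom is a 10 cm water cube on a 2 mm voxel mesh (50³ voxels) holding
a 2 cm cubic target (1000 voxels, 8 cm³). The beam enters the +z face and
propagates toward −z; "upstream" displacements are +z (shallower), and
transverse displacements are along +x. A voxel belongs to the target iff its
center lies inside the displaced target cube; displacement steps are integer
multiples of the voxel size, so the target volume is exactly conserved under
every canonical displacement.

The target is filled with Dotarem: gadoterate meglumine (empirical formula
C₂₃H₄₂O₁₃N₅Gd, 753.86 g/mol) at 0.5 mmol/mL in water, total density
1.1753 g/cm³. Elemental mass fractions follow from the formula plus the
water solvent. Derived constants:

* Gd number density `n_Gd = 3.011e20 cm⁻³` (linear in concentration).
* Two-isotope thermal capture cross section
  `σ = 0.148 × 60,900 + 0.157 × 254,000 = 48,891 b` (¹⁵⁵Gd, ¹⁵⁷Gd; the
  shipped table carries all seven natural isotopes, with the ¹⁵⁶Gd abundance
  trimmed by 5×10⁻⁴ so the abundances sum to one).
* Macroscopic capture cross section `Σ_a = n_Gd σ = 14.72 cm⁻¹`
  (mean free path ≈ 0.68 mm — the optically thin treatment of the target is
  therefore a deliberate linearization, see §6).
* Relative stopping power (RSP) by Bragg additivity of Bethe mass stopping
  powers at 80 MeV, normalized to water: **1.1270**. Water is exactly 1 by
  construction, and RSP is exactly proportional to density at fixed
  composition.
* 43 keV linear attenuation from an elemental μ/ρ mixture rule:
  water 0.267 cm⁻¹ (half-value layer ≈ 2.6 cm), Dotarem 0.528 cm⁻¹.
  Materials may instead declare an HVL override (`μ = ln 2 / HVL`).

## 2. Dose engine

Range-energy relation: Bragg-Kleeman, `R = α E^p` with `α = 0.0022 cm/MeV^p`
and `p = 1.77`, calibrated against an embedded CSDA range table for water
(50–100 MeV, agreement within 2 %); a tabulated override is supported.

Depth dose per proton is the power-law stopping power of the Bragg-Kleeman
model convolved with Gaussian range straggling `σ_R = 0.012 R`:

```
D(d) = Φ(d) ∫ S(u) φ(u − (R − d); σ_R) du,   S(u) = q u^(q−1) / α^q,  q = 1/p
```

The substitution `v = u^q` removes the integrable end-of-range singularity,
so a fixed 64-node Gauss-Legendre rule converges rapidly; the convolved
Bragg peak sits a fraction of a millimetre proximal of `R` (within one
voxel). `Φ(d) = 1 − λ·min(d, R)` is the surviving primary fluence with
`λ = 0.005` per WE cm — protons removed by nonelastic nuclear interactions,
whose energy is treated as not locally deposited. The depth integral of the
curve therefore equals `E (1 − λR/(1+q))`, which the tests verify to 0.1 %.

Lateral spread is a depth-dependent Gaussian, `σ(d) = σ₀ + k·d` with
`σ₀ = 4 mm` at the entrance and `k = 0.45 mm/cm` as a multiple-Coulomb-
scattering stand-in; voxel doses use the exact Gaussian integral over each
voxel cross-section (error-function bands), not midpoint sampling. Depth is
water-equivalent, accumulated by ray tracing `RSP × voxel length` along the
beam axis.

## 3. Planner

Energy layers are anchored at the distal target edge and stepped upstream in
2 mm WE increments until the proximal edge: 11 layers for an all-water
target (peak depths 6.0 → 4.0 cm, 87.3 → 69.4 MeV) and 12 for the Dotarem
target (distal WE depth 4 + 2×1.1270 = 6.254 cm, distal energy 89.4 MeV).
Each layer carries the same 3 mm lateral lattice covering the 2×2 cm² target
cross-section: 49 positions with x, y ∈ {−9, …, +9} mm, hence 539 / 588
spots.

Spot weights solve the nonnegative least-squares problem
`min ‖A w − 4 Gy‖², w ≥ 0` over the 1000 target voxels, with `A` the
per-proton influence matrix. The solver is an accelerated projected-gradient
(FISTA) iteration with adaptive restart and a cyclic coordinate-descent
polish; it is cross-checked in the tests against a Lawson-Hanson solver on
random problems and against its own KKT conditions on the full plan. The
optimal set of this degenerate problem is convex and closed under the
lateral reflections x → ±x, y → ±y, so the solution is averaged over that
group, making the shipped plan exactly reflection-symmetric. Mean target
dose: 3.997 Gy; D90: 3.83 Gy; total fluence 1.59×10¹⁰ protons.

## 4. Emission and detection

**PIXE channel.** Expected Kα1 photons per spot:
`Y = Σ_vox Φ·n_Gd·σ_K(E(d))·Δℓ·ω_K·f_Kα1`, with the K-shell ionization
cross section σ_K(E) log-log interpolated from an embedded 10-point table
(5–250 MeV, 0.05 → 80 b, monotone over the clinical window). The table above
~15 MeV is a modelled extension (config-replaceable), and `ω_K = 0.93`
(K fluorescence yield), `f_Kα1 = 0.48` (Kα1 branch) are literature-typical
constants shipped as defaults. The yield is exactly linear in spot weight
and in Gd concentration.

**Capture channel.** Neutron production along each proton track scales as
`w·y₉₀·(E/90)²` per cm with `y₉₀ = 2×10⁻⁴` neutrons/(proton·cm) — an
a-priori normalization chosen before any acceptance measurement, making the
default 43 keV tally PIXE-dominated (capture ≈ 14 % of the detected total).
Thermal transport uses the screened first-flight kernel
`exp(−r/L)/(4πr²)` with diffusion length `L = 2.8 cm`; captures in the
target voxels are `Σ_a × kernel × volume` (optically thin linearization),
each yielding `0.5991 × 0.8 × ω_K × f_Kα1` photons at 43 keV (internal
conversion yield × K-vacancy fraction). The kernel is validated against a
first-flight Monte-Carlo track-length oracle in the tests.

**Detection.** Every emission voxel is averaged over 128 fixed
Fibonacci-sphere directions; each ray accumulates `exp(−Σ μᵢ dᵢ)` through
water and target (slab-method box intersections) out to an 8.7 cm scoring
sphere that must enclose the phantom (half-diagonal 8.66 cm). Vacuum outside
the phantom does not attenuate, so detection never creates counts and one
water HVL halves the intensity exactly. A spectrum synthesizer
(Gaussian-broadened 43/49/79.5/181.9 keV lines over an exponential
continuum, Poisson-sampled per bin) and a sideband line extractor support
counting-statistics studies.

## 5. Scenario engine and reproducibility

Scenarios hold the plan fixed in room coordinates while the target material
assignment moves (±10 mm, 2 mm steps; transverse +x or longitudinal z).
Every result records the md5 hash of the spot list, and the analysis
functions refuse to compare results from different plans. Sampled mode draws
the delivered protons per spot and the detected counts from Poisson
distributions in per-spot RNG substreams keyed by `(seed, spot_id, draw)`,
so results are reproducible bit-for-bit given the seed, independent of
execution order, and never disturb the caller's RNG stream.

Typical single-core wall times: plan optimization ≈ 5 s; one scenario ≈ 2 s;
the transverse series ≈ 11 s; the longitudinal series ≈ 20 s; the full
`run_study()` bundle ≈ 40 s.

## 6. Modelling decisions and limits

* **Surrogate, not transport.** No Monte-Carlo particle transport: scattered
  dose halos, nuclear secondaries' local dose, neutron moderation physics
  and detector response are all collapsed into a few constants
  (`λ`, `k`, `y₉₀`, `L`). Absolute fluences and count rates are indicative;
  the study's object is the *relative* dose-signal behaviour.
* **Corner-weight share.** Under the 4 mm Gaussian entrance spot, the
  converged NNLS optimum places 52.8 % of the target dose in the four corner
  spot stacks; reference plans computed under a full Monte-Carlo beam model
  report ≈ 74 %. The gap is a beam-model property (broader effective lateral
  profiles force more edge weight), verified not to be a convergence
  artifact, and is reported rather than tuned away.
* **Optically thin target.** With a 0.68 mm capture mean free path the
  2 cm target is in reality strongly self-shielding; the linear kernel
  deliberately ignores this so that the capture channel, like PIXE, is
  linear in concentration. Trends, not absolute capture rates, are the
  modelled quantity.
* **Kinetic-energy ordering.** Target-entry kinetic energy decreases as the
  target moves downstream (deeper), and the per-spot dose-signal slope
  increases strictly with entry energy — the physical ordering implied by
  the range-energy relation and the monotone σ_K.
* **Corner coordinates.** Lattice positions are expressed in mm; the corner
  stacks sit at (±9, ±9) mm on the 3 mm lattice.
* **Nuclear fluence loss.** `λ = 0.005` per WE cm (≈ 1–2 % over clinical
  ranges) keeps the engine's stated energy-conservation property exact;
  it is a config knob, not a fitted value.
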