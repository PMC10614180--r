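---
title: "Quasi-centroid corrections to classical water dynamics: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-centroid corrections to classical water dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Vibrational (infrared) spectra of liquid water and ice are shaped by nuclear
quantum effects: zero-point motion in the stiff O–H stretch red-shifts the
stretching band by on the order of 100 cm⁻¹ relative to purely classical
dynamics on the same potential. Imaginary-time path-integral sampling captures
the quantum *statistics* exactly but provides no real-time dynamics; centroid
molecular dynamics (CMD) recovers approximate dynamics by propagating the
ring-polymer centroid on its potential of mean force, but suffers from the
well-known *curvature problem*: at low temperature the ring polymer spreads
around angular coordinates, the centroid of a bent molecule slides off the
arc of physical geometries, and stretching bands artificially red-shift and
broaden.

Quasi-centroid molecular dynamics (QCMD) cures this by averaging the beads in
*curvilinear* coordinates: for each water molecule the quasi-centroid is the
geometry with bond lengths `r̄ᵢ = (1/P) Σⱼ rᵢ⁽ʲ⁾` and bond angle
`θ̄ = (1/P) Σⱼ θ⁽ʲ⁾`. The fast variant implemented here (f-QCMD) avoids
on-the-fly adiabatic propagation entirely. It has three stages:

1. **PIMD targets.** A thermostatted path-integral MD run samples the
   quasi-centroid distribution functions at the target state point: the three
   intermolecular radial distribution functions `g_OO`, `g_OH`, `g_HH`
   between quasi-centroid sites, and the intramolecular densities `ρ_r` (of
   `r̄`, both bonds) and `ρ_θ` (of `θ̄`). To place quasi-centroids in space,
   each molecule's rigid quasi-centroid geometry is set at the
   Cartesian-centroid molecule's center of mass and oriented by the
   mass-weighted optimal rotation (quaternion eigenproblem) onto the centroid
   molecule.
2. **Regularized IBI.** The quasi-centroid potential of mean force is written
   as `V_qc = V_cl + ΔV_intra + ΔV_inter`, with `ΔV_intra` separable per
   molecule (a quartic polynomial in `r − r_eq` per bond — the same degree as
   the model's own stretch polynomial — plus a quadratic in `θ − θ_eq`) and
   `ΔV_inter` a sum of tabulated pair terms `ΔV_OO`, `ΔV_OH`, `ΔV_HH`.
   Iterative Boltzmann inversion adjusts these so that *classical* NVT
   sampling on `V_qc` reproduces the PIMD targets: the pair tables are
   updated by `kT · ln[(g⁽ⁱ⁾ + εG)/(g_target + εG)]`, where `G` is the larger
   of the two maximum peak heights, and the intramolecular polynomials by a
   density-weighted least-squares refit of `kT · ln(ρ⁽ⁱ⁾/ρ_target)` over the
   bins where both densities exceed 1% of their maxima. The `εG` term damps
   noise-driven updates where the distributions are small, which is what
   keeps the iteration stable.
3. **Spectra.** Classical MD on `V_qc` yields the dipole absorption spectrum
   from the dipole-derivative autocorrelation function, damped with a Hann
   window and cosine-transformed. Comparing against classical MD on `V_cl`
   isolates the nuclear-quantum shifts.

The central identity making stage 2 legitimate is that quasi-centroid
distribution functions are the same whether the average is taken over a
classical NVT ensemble on the exact quasi-centroid potential of mean force or
over the PIMD ensemble with quasi-centroids constructed from the beads. IBI
therefore has a consistent fixed point; what is approximate in f-QCMD is the
*separable, pairwise form* assumed for the correction.

## The water model

The classical reference potential is the flexible four-site q-TIP4P/f model
(parameters in `inst/extdata/qtip4pf.params`, from the model's defining
publication): a quartic Taylor expansion of a Morse potential for each O–H
stretch, `D[a²δ² − a³δ³ + (7/12)a⁴δ⁴]`; a harmonic bend; Lennard-Jones
between oxygens; and point charges on the hydrogens plus a massless M site at
`γ r_O + (1−γ)(r_H1 + r_H2)/2` carrying `−2 q_H`. Forces on the M site are
redistributed to O and H by the chain rule. The system dipole is the
charge-weighted sum over sites, which for neutral molecules reduces to
`q_H γ (d₁ + d₂)` per molecule with `dᵢ` the O→Hᵢ displacement; its analytic
time derivative feeds the spectra.

**Electrostatics.** Real-space damped-shifted-force (DSF, Wolf-style) Coulomb
with cutoff defaulting to half the smallest cell edge and damping
`α = 2/r_cut` (the usual damping-times-cutoff ≈ 2 criterion; at desk-scale
cutoffs weaker damping leaves a visible structural artifact in the `g_OO`
tail). Each site pair uses its own minimum image, and each pair term is
tapered by a quintic switch over the last 1 a0 so the potential is C² at the
cutoff — both choices are what keep multi-10-ps NVE runs drift-free.
Lennard-Jones is force-shifted. Full Ewald summation is deliberately *not*
provided: every observable this package reports is a band position, which at
these system sizes is insensitive to the real-space treatment, and a single
electrostatics path keeps the compiled core small and uniformly tested.

**Units.** Hartree atomic units internally; fs, K, Å, kcal/mol and cm⁻¹
appear only at the interfaces (`fqcmd_units()` collects the conversions).

## Propagation

Classical dynamics uses velocity Verlet (`dt = 0.25` fs throughout), with an
optional local stochastic (Langevin) thermostat in the BAOAB splitting,
default friction time constant 100 fs. Spectra are always computed from NVE
segments launched from thermostatted snapshots, so the thermostat cannot
distort line shapes; segment count, lengths and the re-randomization
stretches between segments are parameters of `spectrum_from_segments()`.

PIMD uses the convention in which every bead feels the full physical
potential and the composite system is sampled at inverse temperature `β/P`
(spring frequency `ω_P = P/βħ`); static bead averages then converge to exact
quantum thermal averages as `P → ∞`. The integrator is the OBABO splitting:
half-step per-normal-mode stochastic thermostat (internal modes critically
damped at `2ω_k`, the centroid mode weakly coupled), half-step force kick,
exact free-ring-polymer evolution in normal modes, and the mirror
half-steps. `P = 32` at 300 K and `P = 64` at 150 K are the production
values; scaled-down runs use `P = 8–16`, which captures most but not all of
the stretch zero-point spread (`βħω ≈ 17` for the O–H stretch at 300 K), so
reduced-scale red shifts are expected to sit somewhat below fully converged
ones.

## Numerical choices that matter

- **Pair-correction tables.** Uniform radial grids starting at the first bin
  where the target `g` exceeds 10⁻⁴ and ending at the cutoff, evaluated with
  a C¹ cubic-Hermite interpolant whose nodal derivatives come from a natural
  cubic spline. Below the inner edge the table continues linearly (constant
  force) and the event is counted, never thrown, so rare close approaches
  cannot kill a trajectory. Each IBI *increment* (not the accumulated table)
  is smoothed with a Savitzky–Golay filter (window 9 bins, cubic) and
  switched to zero over the last 1 a0 with a quintic switch; smoothing the
  increment only preserves the exact IBI fixed point: if trial and target
  coincide, the table is left bit-for-bit unchanged.
- **Intramolecular polynomials.** The refit coefficients are trusted only on
  the coordinate interval that informed the fit (the ≥1%-density region);
  outside it the polynomial continues linearly. Without this clamp the
  quartic tail can turn attractive and a single thermally stretched bond
  diverges mid-iteration.
- **Convergence metric.** Per channel, the sup-norm of the difference
  between lightly smoothed trial and target curves, weighted by the
  normalized target density (so empty regions do not dominate); the
  intramolecular densities are scaled by their target maxima first to make
  the metric dimensionless and comparable to `g`. Five consecutive
  increases abort the fit with the advice to raise ε — the documented
  instability mode of unregularized IBI.
- **ρ_θ convention.** A plain histogram of `θ̄` without a `sin θ` Jacobian:
  target and trial use the identical estimator, so any smooth Jacobian
  cancels in the IBI log-ratio and cannot move the fixed point.
- **Bin widths.** 0.02 a0 for `ρ_r`, 0.5° for `ρ_θ`, 0.05 a0 for the RDFs —
  fine enough that statistical noise, not resolution, limits the fit.
- **Spectra.** The Hann taper is `cos²(πt/2τ)`, reaching zero at `t = τ`
  (600 fs for the liquid, 800 fs for ice). The correlation function is
  averaged over all time origins with unbiased lag normalization and over
  independent NVE segments; the cosine transform is zero-padded (factor 8)
  and tiny negative lobes from the finite window are clamped to zero.
  Spectra are peak-normalized and the constant absorption prefactor
  (temperature and frequency factors) is omitted — every observable here is
  a band position, extracted by a three-point parabolic refinement of the
  maximum in a stated search window.
- **Seeds.** Every stochastic component draws from one master seed through a
  deterministic derivation, so stages, resumed IBI fits and reruns are
  exactly reproducible.

## What the generators emulate — and what they do not

`build_liquid_box()` places equilibrium-geometry molecules on a jittered
lattice with random orientations at the reference density
(216 molecules / 35.24³ a0³), draws Maxwell–Boltzmann velocities and
pre-equilibrates briefly; downstream runs must still equilibrate to the
liquid state (a few ps at 300 K) before sampling. `build_ice_cell()` puts
oxygens on the hexagonal-diamond lattice in the orthohexagonal setting tiled
exactly to the printed 96-molecule cell, assigns protons by a seeded repair
walk until the Bernal–Fowler rules hold (two covalent H per O, one H per
hydrogen bond), and then reverses directed loops in the hydrogen-bond graph
until the net dipole is below 0.5 e·a0 — a proton-disordered,
near-apolar realization. Real ice samples differ in their particular proton
topology; band positions are insensitive to the realization, which is why
the seed only needs to be recorded, not chosen.

The toy systems are oracles, not physics: the one-dimensional oscillator has
closed-form classical and quantum position variances for validating the PIMD
machinery, and the Lennard-Jones fluid with a known Gaussian pair
perturbation provides a ground-truth recovery test for the IBI loop. On the
recovery test the fluid is kept at moderate density (ρ* = 0.4) deliberately:
in a dense liquid the IBI log-ratio update is renormalized by indirect
correlations (a measured per-iteration gain well below one), so full
amplitude recovery within a test-sized iteration budget requires conditions
where the direct Boltzmann relation is a good first approximation. This is a
property of the IBI update itself, not of the implementation.

Passing tests on these systems demonstrate correct statistics, forces,
transforms and fixed points; they do not certify the *physical* accuracy of
f-QCMD beyond what the separable pairwise correction can express, nor
convergence of desk-scale runs with respect to box size, bead count or
sampling length.

## Problem sizes used by the test suite

The suite runs everything at reduced scale, chosen once from
statistical-error estimates: the classical liquid spectrum uses 64 molecules
with ~21 ps of NVE segments; the full reduced f-QCMD pipeline uses
64 molecules, `P = 16`, a 1.5 ps PIMD target run, 10 IBI iterations at
`ε = 1` with 2 ps trials, and 9 ps of NVE segments per potential; the ice
spectrum uses the printed 96-molecule cell with 12 ps of segments. The
production-scale protocol (216-molecule liquid, `P = 32/64`, 30 iterations)
runs through exactly the same code via `run_stage()` and a configuration
file; only the numbers differ.

## Known limitations

- The velocity-Verlet shadow energy of the charged, stiff-stretch system
  diffuses slowly at `dt = 0.25` fs (about 10⁻⁵ hartree over 10 ps at
  64 molecules, a few 10⁻⁵ kT per degree of freedom). This is the
  integrator's noise floor — it is independent of the electrostatics
  damping and scales as `dt⁴` — not a discontinuity in the potential.
- Desk-scale boxes with half-box cutoffs leave percent-level structure in
  the RDF tails; with the `α·r_cut ≈ 2` damping the residual is a few
  percent at 64 molecules.
- Reduced bead counts under-converge the stretch zero-point spread, so
  reduced-scale anharmonic red shifts sit below production values.
- Distribution estimation uses plain histograms; the low-variance
  force-based estimators that make production IBI cheap are out of scope,
  compensated here by longer trial trajectories.
- Overtone and combination bands are outside the reach of all centroid
  methods (intensities especially) and are not addressed.
- The IBI solution is not proven unique for this multi-channel correction;
  ε-sensitivity of the fitted `V_qc` is surfaced in the fit history, and
  the method-level claim is only that *spectra* are insensitive within the
  convergence domain.
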