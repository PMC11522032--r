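---
title: "Coarse-grained tensile mechanics of cross-linked collagen fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained tensile mechanics of cross-linked collagen fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`fibrilmd` simulates destructive tensile tests of collagen fibrils at the
coarse-grained bead-spring level. A tropocollagen (TC) molecule is a chain
of beads 14.0 Å apart (one bead per a few amino acids, 1358.7 amu each);
molecules are replicated over a triangular-lattice cross-section and
staggered axially by whole multiples of the D-period (67 nm) in the
characteristic 5-staggered packing, with a gap of 0.6 D between successive
molecules on the same lattice line. The total energy is

E = Σ Φ_bond(r) + Σ Φ_angle(φ) + Σ Φ_pair(r),

with three interaction kinds:

* **Bonds** (backbone, reinforced end extensions, divalent and trivalent
  enzymatic cross-links, AGE cross-links) follow a breakable trilinear
  tension law: stiffness k₀ up to the critical hyperelastic distance r₁,
  stiffness k₁ up to the breaking distance r_break, then a linear ramp
  from the peak tension to zero over a = z·(r_break − r₁). The force is
  continuous everywhere and identically zero beyond r_break + a. A bond
  is *flagged broken* at its first crossing of r_break (the onset of the
  softening ramp) and removed from force evaluation once past
  r_break + a; broken bonds never re-form. The z = 0.05 regularization is
  small enough that the ramp is a numerical device, not a mechanical
  feature.
* **Angles** are harmonic in the triplet angle, E = k_B (φ − φᵢ)², with
  per-triplet equilibrium angles φᵢ recorded from the built geometry
  (170°–180°). The factor-2 convention (moment 2 k_B Δφ) is the default;
  the ½k convention is available via `angle_law(convention = "half")`
  because the source literature is ambiguous on this point.
* **Non-bonded pairs** interact by a 12-6 Lennard-Jones potential with a
  soft core: below λσ (λ = 0.9) the force is held at its λσ value, which
  bounds the repulsion encountered during insertion and rupture events.
  The potential is truncated at 2.5 σ and shifted so the energy is zero
  at the cutoff (the shift, not the bare potential, is what the dynamics
  integrate; `pair_energy(shifted = FALSE)` exposes the textbook form
  whose zero crossing is exactly σ). Directly bonded pairs are excluded
  from the pair sum to avoid double-counting stiffness at bonded
  contacts.

All parameters ship in `inst/extdata/forcefield_params.yaml` (energies in
kcal/mol, lengths in Å, mass in amu); any entry can be overridden through
`default_forcefield(overrides = ...)`. Stress is carried natively in
kcal mol⁻¹ Å⁻³ and converted to MPa only for reporting
(`stress_to_MPa()`, 1 kcal mol⁻¹ Å⁻³ = 6947.7 MPa).

## Geometry generation

The published geometry derives molecule axes from a crystallographic
microfibril model; this package replaces that input with a synthetic
generator (an optional PDB reader, `read_reference_structure()`, is
provided). `build_molecule()` marches beads along a gently turning
tangent so consecutive beads are *exactly* r₀ apart; the turning angle is
an alternating-sign zigzag with a slowly modulated amplitude, which makes
the sampled equilibrium angles sweep the full 170°–180° range while
keeping lateral excursions near 1 Å (so neighbouring molecules at the
15.45 Å lattice spacing never overlap). The lattice spacing default of
15.45 Å is tuned so the full 20.2 nm cross-section hosts ~155 molecules;
the spacing itself is not a published quantity.

Molecule ends terminate in four telopeptide beads (the only enzymatic
cross-linking sites). Each lattice line is extended by 40 reinforced
beads per end (same law as the backbone but r_break = 70 Å) so that force
can be introduced without breaking chains at the grips, and the outermost
10 beads of every chain ending within one D-period of a fibril end form
that end's rigid clamp.

Two geometric identities of the published model are mutually
approximate: 218 beads at 14.0 Å span 4.53 D, while a 0.6 D gap implies a
4.4 D molecule. The builder enforces the bead spacing and the 0.6 D gap
exactly and lets the line period be molecule extent + gap; stagger
offsets remain exact multiples of D, so the measured banding period is
exactly D.

## Cross-link insertion

Enzymatic cross-links (ECLs) anchor at randomly selected terminal
telopeptide beads — `ecl_content` percent of all ends, 100% meaning the
nominal two per molecule — and attach to the nearest helical bead of the
nearest distinct molecule within the capture radius (trivalent: the two
nearest distinct molecules). AGE cross-links are placed uniformly over
all eligible helical–helical bead pairs of different molecules within the
capture radius, with exactly `round(n_age × n_molecules)` bonds;
densities below one per molecule draw host molecules first. Telopeptide
and extension beads are never AGE binding sites. The capture radius
defaults to 2 r₀ = 28 Å, which restricts partners to adjacent lattice
lines. On a finite bundle the outward-facing terminal ends have no
foreign helical bead in range at any sensible radius; such ends are
skipped and counted in a shortfall report rather than silently linked.

## Simulation protocol

`run_protocol()` executes build → minimize (steepest descent, then
Polak–Ribière conjugate gradient) → NVT equilibration → cross-link
insertion → re-equilibration → tensile test; insertion before the first
equilibration is structurally rejected. Dynamics are velocity-Verlet
with a Langevin thermostat at 300 K applied to non-clamp beads.

The thermostat is *profile-unbiased*: the O-step damps and re-noises only
the fluctuation of each bead about its molecule's instantaneous mean
velocity. A conventional Langevin bath exerts a viscous drag on the
coherent sliding of whole molecules; at desk-scale pulling speeds that
artificial drag is comparable to the fibril's entire stress response and
buries the post-yield softening that intra-fibrillar sliding produces.
Molecular drift modes remain coupled to the bath indirectly through the
intermolecular forces.

During the pull the two rigid clamps move apart along the fibril axis at
constant speed; engineering stress is the mean of the two clamp force
magnitudes over the construction cross-section area (π d²/4), and global
strain is the clamp-separation change over its value at the start of the
pull (i.e. after the post-insertion equilibration). A run ends when the
smoothed stress falls below 5% of its running peak, or at the configured
strain cap.

## Desk-scale presets and what they can show

The published protocol (155 molecules, 80 ns equilibration, 1 fs tensile
steps at 10 m/s) is cluster-scale; it is retained as the non-default
`"full"` preset and is not exercised by the tests. All tests and the
acceptance analyses run the `"mini"` preset:

* 7 lattice sites (one central + hexagon), two molecules per line;
* molecules of 97 beads, spanning 96 × 14 Å ≈ 2 D-periods, so that every
  line carries an interior gap junction — the weak planes of the
  staggered packing — and the system still hosts enough molecules (14)
  for cross-link failure *fractions* to be measurable;
* equilibrations of 0.04 ns (10 fs steps) and 0.03 ns after insertion;
* tensile pulling at 2.5 × 10⁻⁴ Å/fs (25 m/s — 2.5× the published,
  already upscaled, speed) with 20 fs steps. The stiffest interaction
  (backbone, k₁ = 97.66 kcal mol⁻¹ Å⁻²; 1358.7 amu beads) has a
  vibration period of ≈1.1 ps, so 20 fs resolves it ~57 times per
  period; microcanonical drift checks in the test suite run at 1 fs.

These choices keep a full build–equilibrate–pull cycle near two minutes
on one core. What survives the scale-down, and what the passing tests
therefore demonstrate, is the *mechanistic* contrast: stress–strain
curves that coincide in the initial linear regime regardless of AGE
density; softening, sliding-dominated failure with substantial AGE/ECL
rupture and intact backbones at low AGE density; stiffening beyond the
elastic limit, higher peak stress, suppressed sliding and eventual
backbone rupture at high AGE density. Absolute stresses, work to
failure, and the precise failure fractions carry desk-scale and
arrangement noise of tens of percent, and seed-replication is reduced to
three seeds per condition (one or two arrangements per condition in the
test battery); nothing at this scale validates absolute magnitudes
against experiments. One small-bundle effect deserves emphasis: when a
fibril of only seven molecules fails by sliding, the slip localizes
onto a single molecule-scale interface and only the cross-links crossing
that interface ever load to rupture, so per-arrangement failure
fractions scatter widely (and tend to sit below the distributed-sliding
values a 155-molecule bundle produces, where no cross-section is free of
cross-links).

## Analysis conventions

* Stress curves are smoothed by a centred moving average over a
  0.002-strain window before peak extraction; raw curves are always kept.
* The elastic-limit strain ε₀ defaults to the fixed value 0.15; the
  detection policy fits the initial modulus on ε ∈ [0.02, 0.10] and
  reports the first strain where the running tangent (symmetric
  difference over ±0.01 strain) deviates by more than 10%, sustained for
  0.01 strain. The tangent window means detection can lead a sharp
  transition by up to half a window.
* Work to failure integrates the raw stress by trapezoids up to the
  failure strain (first post-peak strain with smoothed stress below 5% of
  the peak; if a run ends earlier the metrics are flagged partial and the
  last strain is used).
* Δσ = σ_peak − σ(ε₀), floored at zero; σ(ε₀) is interpolated linearly.
* Per-species force histories average the tension over *intact* bonds of
  each species; failure fractions divide cumulative flagged-broken counts
  by the initially inserted count per species.
* The sliding decomposition reports ε_TC (mean strain of intact helical
  backbone bonds; extension bonds excluded) and Δε = ε − ε_TC. In this
  implementation sliding manifests as Δε growing *positive* past ε₀ —
  molecular stretching lags the imposed strain, and bond recoil after
  rupture amplifies the lag. The source literature describes the same
  mechanism with the opposite sign; the package reports the quantity as
  defined here and leaves the sign convention explicit.

## Known limitations

Synthetic waviness is a statistical stand-in for crystallographic
molecule axes; divalent and trivalent ECLs are not mixed within one
fibril; AGE chemistry is reduced to a single representative bond law;
there is no solvent, mineral phase, or radius-dependent cross-link
density; clamp capture on a finite bundle leaves a few outward-facing
telopeptide ends without cross-link partners; and the 5% stress-drop
failure criterion can remain unreached in strongly sliding systems
within the strain cap, in which case summary metrics are flagged
partial.
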