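# fibrilmd

Coarse-grained steered molecular dynamics of cross-linked collagen
fibrils in R.

Collagen fibrils are staggered bundles of tropocollagen (TC) molecules
held together by enzymatic cross-links (ECLs) at the molecule ends and —
with age and diabetes — by advanced glycation end-product (AGE)
cross-links in the helical regions. `fibrilmd` builds bead-spring fibril
models with the D-periodic 5-staggered geometry, inserts both cross-link
families at configurable densities, pulls the fibril apart between rigid
clamps, and analyses how the cross-link network changes stiffness,
strength, energy dissipation and the failure mechanism. It is aimed at
researchers studying fibril-scale mechanics of collagenous tissue
(bone brittleness, tendon stiffening) who want a desk-scale, fully
scriptable model rather than a cluster-scale MD setup.

## Model

The total energy is `E = Σ Φ_bond + Σ Φ_angle + Σ Φ_pair`:

* bonds follow a breakable trilinear tension law
  `F(r) = k0 (r − r0)` up to `r1`, continuing with slope `k1` to
  `r_break`, then ramping linearly to zero over `a = z (r_break − r1)`;
  separate parameter sets for the TC backbone, reinforced end
  extensions, divalent/trivalent ECLs and AGEs (glucosepane as the
  representative);
* angle bending is harmonic, `E = k_B (φ − φ_i)^2`, about per-triplet
  equilibrium angles recorded from the built geometry (170–180°);
* non-bonded packing is a soft-core 12-6 Lennard-Jones interaction,
  truncated and shifted at 2.5 σ.

Dynamics are velocity-Verlet with a profile-unbiased Langevin thermostat
(300 K) and rigid end clamps displaced at constant velocity; engineering
stress is the clamp force over the construction cross-section area.
Units: Å, fs, kcal/mol, amu; stress converts to MPa via
`stress_to_MPa()`.

## Worked example

A single desk-scale experiment — build, equilibrate, cross-link at 10
AGEs per molecule, pull:

```r
library(fibrilmd)

run <- run_experiment(list(preset = "mini", n_age = 10, ecl_content = 0,
                           ecl_valence = "divalent", seed = 42))
summarize_mechanics(run)
#> <fibril_metrics> sigma_peak=0.3984 @ eps=0.281 | W_f=0.07795 | eps0=0.150
#>   sigma_0=0.1877 dsigma=0.2106 | fail @ 0.500 (partial)

detect_linear_limit(stress_strain(run))$eps0
#> [1] 0.1305863
```

Read: the fibril responds linearly up to a global strain of about 0.13,
then stiffens (the elastic-to-peak stress difference Δσ ≈ 0.21
kcal/mol/Å³ is over half the peak stress of 0.40 kcal/mol/Å³ ≈ 2.8 GPa
at this coarse-grained force field), and peaks at 28% strain — the
AGE-stiffened failure mode; the run ends at the preset's 0.5 strain cap
with the post-failure tail still above the 5% stress-drop criterion,
so the metrics carry a `partial` flag. The same call with `n_age = 0.5`
instead softens after the elastic limit and fails by intermolecular
sliding at larger strain with Δσ near zero.

The `analysis/` scripts chain these calls into the full study: geometry
verification (`01`), a single instrumented run (`02`), the AGE-density
sweep (`03`), and the failure-mechanism contrast with per-species force
histories, broken-bond fractions and the sliding decomposition (`04`).
Each writes tables (and figures, via `report_runs()`) under `results/`.

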