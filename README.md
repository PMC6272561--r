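# coopbind

Cooperative-binding analysis of protein–ligand conformational ensembles in
R: end-state binding free energies (MM-PB/SA and MM-GB/SA) with per-residue
decomposition, π–π stacking geometry, close-contact occupancy,
hydrogen-bond and RMSD/RMSF statistics — plus a synthetic-ensemble
generator with ground-truth manifests so the whole pipeline is testable
without molecular dynamics trajectories.

## The scientific problem

Some drug-metabolizing enzymes — cytochrome P450 3A4 (CYP3A4) is the
canonical case — can bind two copies of a substrate at once. The second
copy modulates the binding of the first ("cooperative binding"), often
through aromatic π–π stacking between the ligand copies and active-site
phenylalanines, and shows up as a more favourable binding free energy for
the first copy. Quantifying that effect from a conformational ensemble
requires (a) end-state free energy estimates, (b) per-residue attribution,
and (c) geometric evidence: ring–ring distances and inter-plane angles,
contact occupancies, hydrogen-bond lengths.

`coopbind` implements the standard end-state estimator on the
single-trajectory protocol. For each ensemble frame the complex, receptor
and ligand are scored on the same geometry, so bonded terms cancel and

```
ΔG_bind = ΔE_ele + ΔE_vdw + ΔG_polar + ΔG_nonpolar        (−TΔS ≡ 0)
```

with Coulomb (k_e = 332.0637 kcal·Å/mol·e²) and 12-6 Lennard-Jones gas
terms, polar solvation from either a generalized Born model
(Hawkins–Cramer–Truhlar pairwise descreening radii + Still's pairwise
formula) or a finite-difference linearized Poisson–Boltzmann solver
(SOR, harmonic dielectric interface averaging, compiled core), and a
nonpolar term γ·SASA + β from Shrake–Rupley surface areas. The GB path is
pairwise-decomposable: per-residue contributions sum to the total ΔG_bind
exactly (to 1e-6 kcal/mol per frame). Two study arms (normal vs
cooperative) are compared by ΔΔG with a seeded two-sided permutation test.

Geometric analyses follow the conventions of the cooperative-binding
literature: two rings stack when their centroid distance is strictly below
7 Å; a residue is in close contact when its minimum heavy-atom distance to
the ligand is strictly below 5 Å; the inter-plane angle (least-squares
plane normals, folded into [0°, 90°]) classifies pairs as parallel
(< 30°), tilted, or perpendicular (> 60°).

## Worked example

Build a paired synthetic study — a normal arm (one two-ring ligand stacked
on an aromatic pocket residue at 5.07 Å / 40°) and a cooperative arm whose
second ligand copy packs the first 0.47 Å closer and more parallel — then
score both arms:

```r
library(coopbind)
normal <- synthetic_spec(seed = 1, n_frames = 50, jitter_sigma = 0.15)
coop <- synthetic_spec(seed = 2, n_frames = 50, jitter_sigma = 0.15,
  n_ligands = 2,
  stacking_targets = list(list(ligand = 1, receptor_ring = 1,
                               distance = 4.6, angle = 15)))
study <- make_two_arm_study(normal, coop)
bn <- single_trajectory_mmgbsa(study$normal$ensemble)
bc <- single_trajectory_mmgbsa(study$cooperative$ensemble)
bc
#> MM-GB/SA binding free energy (single-trajectory; -T dS_config = 0)
#>   dE_ele           -3.35 +/-  1.85
#>   dE_vdw           -2.75 +/-  2.31
#>   dE_gas           -6.10 +/-  2.55
#>   dG_nonpolar      -1.83 +/-  0.04
#>   dG_sol           -0.32 +/-  0.83
#>   dG_ele_total     -1.84 +/-  1.38
#>   dG_bind          -6.42 +/-  2.22
compare_breakdowns(bn, bc, n_resamples = 999, seed = 7)[c("ddG", "p_value")]
#> $ddG
#> [1] -4.183106   # cooperative arm binds ~4 kcal/mol stronger by design
#> $p_value
#> [1] 0.001
detect_stacking(study$cooperative$ensemble)$summaries[c(1, 11),
  c("partition_a", "partition_b", "occupancy", "dist_mean", "angle_mean")]
#>    partition_a partition_b occupancy dist_mean angle_mean
#> 1     receptor     ligand1         1  4.594054   16.79907
#> 11     ligand1     ligand2         1  4.502648    9.99276
```

The normal arm scores ΔG_bind = −2.24 ± 3.58 kcal/mol, so the designed
tighter stack is recovered both energetically (ΔΔG < 0, permutation
p = 0.001) and geometrically (the receptor–ligand1 pair is detected in
100% of frames at 4.59 ± 0.09 Å, mean angle ≈ 17°, classified parallel).

A full study — RMSD, stacking, contacts, H-bonds, energy tables,
decomposition, cross-arm comparison, TSV/JSON report — runs through
`run_analysis(analysis_config(...))`, or from the shell:

```sh
inst/cli/coopbind synth --spec spec.json --out arm1/
inst/cli/coopbind analyze --config config.json --out report/
```

## Reference tables

`load_reference_energies()` / `load_reference_decomposition()` expose the
published CYP3A4–ketoconazole component tables for the two crystal forms
("cyp3a4t" = 1tqn-based, "cyp3a4w" = 1w0f-based);
`breakdown_identity_check()` verifies the bookkeeping identities on them.
Absolute trajectory-dependent quantities are validated instead by
property-based oracles (Born ion, sphere SASA, naive-loop nonbonded sums,
decomposition conservation, parameter recovery on synthetic ensembles) —
see `vignettes/cooperative-binding-methods.Rmd`.
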