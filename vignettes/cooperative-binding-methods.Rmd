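---
title: "Methods: end-state energetics and stacking geometry for cooperative binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-state energetics and stacking geometry for cooperative binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopbind)
```

# Scope and model

`coopbind` analyses conformational ensembles of a receptor with one or two
copies of a ligand, the setting of cooperative-binding studies on CYP3A4
with ketoconazole-like two-ring drugs. It answers three questions per
study arm: how strongly does the first ligand copy bind (end-state free
energy), which residues carry that binding (decomposition), and what is
the geometric signature (π–π stacking, contacts, hydrogen bonds)?

## Single-trajectory end-state estimator

For every frame of the complex ensemble the complex, the receptor-side
atoms and the ligand of interest are scored *on the same coordinates*
("single-trajectory protocol"). Internal bonded energies are then
identical in complex and species and cancel exactly in

ΔX = X_complex − X_receptor − X_ligand,

which is why the report carries no bond/angle/torsion rows. The per-frame
identities

* ΔE_gas = ΔE_ele + ΔE_vdw
* ΔG_sol = ΔG_polar + ΔG_nonpolar
* ΔG_bind = ΔE_gas + ΔG_sol
* ΔG_ele(total) = ΔE_ele + ΔG_polar

hold to machine precision by construction, and the same identities are
what the acceptance suite verifies on the published component tables.
Configurational entropy (−TΔS) is deliberately set to zero: the arms being
compared are near-identical systems, the published tables carry no entropy
row, and ΔΔG comparisons between arms are the quantity of interest.

**Assumptions.** Single-trajectory scoring assumes the separated species
relax negligibly; it systematically over-stabilizes binding but cancels
largely in normal-vs-cooperative differences. No nonbonded cutoff is
applied (systems here are toy/pocket scale); an MD engine's simulation
cutoff belongs to sampling, not to end-state scoring.

When two ligand copies are present, the default scores the *first* copy
with the second treated as part of the receptor (the convention behind
"binding free energy of the first ligand" in cooperative models);
`include_second_ligand = FALSE` removes the second copy instead, as a
sensitivity analysis. Both modes are exposed because published practice is
ambiguous on this point.

## Energy terms and their parameters

| term | model | key defaults |
|------|-------|--------------|
| ΔE_ele | pairwise Coulomb | k_e = 332.0637 kcal·Å/mol·e²; 1-2/1-3 excluded; 1-4 scaled 1/1.2 |
| ΔE_vdw | 12-6 LJ, rmin/eps combination | 1-4 scaled 1/2 |
| ΔG_polar (GB) | HCT descreening radii + Still's f_GB | offset 0.09 Å; ε_in 1, ε_out 80 |
| ΔG_polar (PB) | FD linearized PB, SOR | spacing 0.5 Å, padding 10 Å, tol 1e-6 |
| ΔG_nonpolar | γ·SASA + β | γ = 0.0072 kcal/mol/Å², β = 0; probe 1.4 Å; 960 sphere points |

All of these are config-exposed through `solvent_params()`; none is named
by the study this package re-implements, so the defaults follow common
force-field practice (Amber-style 1-4 factors, mbondi-like radii in the
synthetic templates).

**Generalized Born.** Effective radii use the Coulomb-field pairwise
descreening integral in its analytic form; the test suite checks it
against direct numerical quadrature. An isolated atom recovers
(intrinsic − offset) exactly, which also fixes the Born-ion limit:
a unit charge with effective radius 2 Å gives −81.978 kcal/mol at
ε_out = 80. Over-descreened atoms (inverse radius ≤ 0) are clamped to
0.1 Å with a warning rather than erroring, since they occur only in
pathological geometries.

**Finite-difference PB.** The linearized equation is discretized with
face-centred dielectrics on a cubic grid and solved by red-black SOR in
compiled code. Two solves per system (solvated and uniform-ε_in
reference) make the reported energy a reaction-field difference, which
cancels the grid self-energy of the point charges. Boundary potentials are
analytic Coulomb/Debye–Hückel values. Two numerical choices matter:

* *Dielectric interface.* Edges crossing an atom sphere get a harmonic
  average 1/ε = f/ε_in + (1−f)/ε_out, with f the in-solute fraction of the
  edge (largest single-sphere coverage). Abrupt painting leaves ~5% error
  on the Born ion at 0.5 Å spacing; harmonic averaging brings it to ~0.6%,
  and halving the grid to 0.25 Å reduces it further (~0.1%) — the
  convergence property the acceptance suite asserts.
* *Relaxation factor.* A fixed ω = 1.6 was considered but converges far
  too slowly on fine grids; the default is the Poisson-optimal
  ω = 2/(1 + sin(π/n)) for grid dimension n, overridable via `sor_omega`.
  Converged answers are identical to the tolerance.

**SASA.** Shrake–Rupley with a deterministic golden-spiral point set.
Sample points are owned by their generating atom; a point lying exactly on
another sphere's surface (within 1e-9) is ceded to the lower-index atom.
This tie-break keeps the *union* area invariant when spheres coincide
exactly — the property the tests assert — at the cost of an arbitrary but
documented attribution of the shared surface. Because the point set has a
fixed orientation, SASA is exactly translation-invariant but only
quadrature-invariant (~1%) under rotation; mirror-symmetric systems
likewise split areas only to quadrature accuracy.

## Per-residue decomposition (GB path)

Ordered-pair gas and GB energies are accumulated per atom — row sums of
the symmetric pair matrix, which splits every unordered pair half-and-half
between partners — and the complex-minus-species change per atom is pooled
into receptor residues plus one ligand self-bucket. Nonpolar contributions
use per-atom SASA differences times γ. The construction conserves the
total exactly: Σ contributions = ΔG_bind per frame (asserted at 1e-6
kcal/mol). The PB reaction field is a global grid quantity with no
per-pair structure, so requesting a PB decomposition is an explicit
unsupported-operation error rather than an approximation.

## Statistical comparison of arms

ΔΔG = mean(ΔG_bind, arm B) − mean(ΔG_bind, arm A) over frames, with a
two-sided permutation test on the pooled per-frame series
(p = (1 + #{|T*| ≥ |T|}) / (n_resamples + 1), fixed seed). A
contingency-table ("Fisher") test is sometimes quoted for such
comparisons, but no contingency table is defined for continuous per-frame
energies, so the permutation test is the package's specification of
"significance" here; its type-I error at α = 0.05 is verified by
simulation in the acceptance suite. The permutation test assumes
exchangeable (effectively independent) frames; for autocorrelated MD
ensembles the user should pre-thin frames, which the `energy_frames`
config field supports.

## Geometry conventions

* **Rings** are simple 5–6 cycles of the bond graph. Perceived rings must
  be planar in the reference frame (RMS out-of-plane ≤ 0.15 Å, the scale
  separating aromatic rings from puckered sp³ rings); explicit ring lists
  in the topology override perception *and skip the planarity screen*, so
  thermal jitter cannot silently drop a known aromatic ring.
* **"Distance between rings"** is centroid–centroid (unweighted member
  mean). The source literature leaves the definition implicit; the
  centroid convention is stated in the outputs.
* **"Angle between rings"** is the angle between least-squares plane
  normals folded into [0°, 90°] (antiparallel ⇒ 0°). This is a
  plane-normal angle, *not* a 4-atom torsion; the literature's "dihedral
  angle between phenyl rings" is undefined, and the two can differ — the
  choice is flagged, not silently equated. Least-squares normals (rather
  than a 3-atom cross product) are robust to puckering.
* **Stacking** requires centroid distance strictly < 7 Å (the aromatic
  interaction criterion); classification thresholds parallel < 30° and
  perpendicular > 60° are conventions — published examples label ~16–31°
  pairs parallel and ~52–58° pairs perpendicular without defining a
  boundary — and are config-exposed. Note a consequence: a 58° pair that
  some authors would call "perpendicular" is classified `tilted` here.
  Per-pair statistics are emitted both over qualifying frames only and
  over all frames, since published averaging practice is ambiguous.
* **Close contacts**: a receptor residue is in contact when its minimum
  heavy-atom distance to the ligand is strictly < 5 Å; hydrogens are
  excluded; all receptor residues are reported explicitly (zeros
  included); fractions are stored as fractions and formatted as
  percentages.
* **Hydrogen bonds**: heavy-atom distance < 3.5 Å and D–H⋯A angle > 120°
  (distance-only mode available). Published reports often give lengths
  only; the angle criterion follows common practice and is config-exposed.
* **RMSD** uses Kabsch superposition (proper rotation enforced) over the
  protein backbone N/CA/C when present, else receptor heavy atoms; the
  reported value is the global minimum over rigid transforms. **RMSF** is
  computed after superposing all frames onto frame 1 (stated in the
  output), about the time-mean position, population-normalized, averaged
  within residues; a separate `fit_selection` lets callers fit on stable
  atoms so mobile atoms do not drag the frame alignment.
* **Ensemble loading** takes all models of a multi-model PDB: the
  equilibration cut and stride that produced an ensemble are the
  producer's concern, and no hidden subsetting is applied
  (`energy_frames` exists for explicit thinning).

## The synthetic world

`synthetic_spec()` states the world the tests assume: a 6-residue pocket
(two aromatic six-ring analogues, one amine-like donor, aliphatic
spacers) on an 8 Å circle; one or two two-ring ligands, each with a
carbonyl-like acceptor oxygen; 200 frames of i.i.d. Gaussian jitter with
σ = 0.2 Å; ligand 1's first ring placed to satisfy its stacking target
(5.07 Å, 40° by default — a typical parallel-displaced aromatic pair)
*exactly* in the base frame; a 2.9 Å donor–acceptor hydrogen bond;
polar-pair charges making the designed interaction net attractive. The
generator records a manifest of per-frame true ring geometries, contact
indicators, the designed H-bond and the designed stronger-binding arm.

What the generator does **not** emulate: bonded constraints (jitter can
distort bond lengths), correlated motions, Boltzmann weighting, water, or
any force-field realism. A green recovery test therefore establishes that
the *estimators* are unbiased within 3 standard errors under known noise
— not that the energetics reproduce any physical system. Monte-Carlo
checks of the recovery contract: the plane-angle estimator carries a small
positive bias (~0.3° at σ = 0.2, well under one standard error of a
200-frame mean), so the 3-SE recovery contract holds in the stated world;
at much larger σ or n the folding bias would eventually dominate the
shrinking standard error.

Randomness uses R's Mersenne-Twister via `set.seed` (a counter-based
generator was considered but base R provides none, and determinism — same
seed, byte-identical output — is the property that matters and is
tested). Caller RNG state is saved and restored around every seeded
operation.

## Published reference tables

The component tables of the CYP3A4–ketoconazole normal/cooperative study
ship as TSV under `inst/extdata/` and are treated as *inputs*: the
original trajectories were never deposited, so absolute energies,
Fe–N distances, H-bond lengths and stacking statistics are not
reproducible at desk scale. What is checkable — and checked — is internal
consistency: every aggregation identity holds on the printed cells to one
printed ulp (0.01 kcal/mol; three cells differ by exactly 0.01 because
components were rounded to 2 dp independently of their totals), and the
published per-residue fold ratios (1.24 for Glu374, 1.86 for Ser119)
reproduce under the report's rounding convention.

That convention is decimal round-half-even on 12 significant decimals of
the stored double: −1.005 renders "−1.00" and −38.855 renders "−38.86",
unlike C `sprintf`, which ties on the binary representation and would
print "−38.85".

## Known limitations

* GB radii are recomputed per species per frame (no caching); fine at
  pocket scale, quadratic in atoms.
* The FD-PB edge-fraction dielectric uses the largest single-sphere
  coverage per edge, slightly underfilling deep sphere–sphere overlap
  seams; Born-ion and refinement tests bound the practical error.
* The permutation comparison treats frames as exchangeable; thin
  autocorrelated ensembles first.
* PDB I/O is deliberately narrow: wwPDB v3.3 fixed columns, no altLocs,
  no insertion codes, no mmCIF, no binary trajectory formats.
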