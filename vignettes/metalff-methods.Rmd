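---
title: "Methods: bonded-model parametrization and conformer analysis in metalff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bonded-model parametrization and conformer analysis in metalff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalff)
```

`metalff` automates the bonded-model description of metal centers: explicit
harmonic bonds and angles between a metal and its coordination shell, point
charges fitted to the electrostatic potential, and van der Waals terms,
assembled into Amber-dialect parameter files, followed by solvation, MD
input generation and RMSD-based conformer clustering.  This vignette
explains the models, the defaults, and the numerical decisions, including
the places where the underlying methods are approximations and what the
test suite does and does not demonstrate.

## Bond perception

Two atoms are bonded when their distance is *strictly* smaller than a
scale factor (default `bond_factor = 0.6`) times the sum of their van der
Waals radii.  The packaged radius table uses Bondi radii for nonmetals
(H 1.20, C 1.70, N 1.55, O 1.52, S 1.80 Å, …) and a uniform 2.0 Å for
every metal.  This combination makes the 0.6 rule chemically sensible:
covalent radii scaled by 0.6 would bond nothing (O–H at 0.96 Å versus a
0.58 Å threshold), whereas with vdW radii the O–H threshold is
0.6·(1.52+1.20) = 1.63 Å and the H···H threshold 1.44 Å, so water gets
exactly its two covalent bonds.  A Cu–N pair at 2.0 Å passes its 2.13 Å
threshold and is recorded as a *metal contact*, never as an adjacency
edge.  The table is a plain TSV in `inst/extdata` and can be replaced via
`element_table(file=)`; symbols missing a radius fall back to 2.0 Å with a
warning so exotic species still parse.

Fragments are the connected components of the metal-free adjacency graph,
found with an explicit-stack depth-first search (no recursion limits on
long chains).  Each metal atom becomes its own singleton fragment — the
alternative of attaching the metal to its nearest ligand would silently
merge ligands that must be parametrized separately.  Metal–metal contacts
are retained in the contact list so polymetallic systems lose no
information.  Per-fragment total charges are user input (configuration or
the CLI `fragment` prompt) and are validated against the system total.

## Seminario force constants

For a bond *i–j* the negated interatomic block
`A = −∂²E/∂r_i∂r_j` (3×3) is eigendecomposed and the eigenvalues projected
on the unit bond vector, `k(i→j) = Σ_m λ_m |û·v_m|`; the two block
directions are averaged.  Interatomic blocks of a real Hessian are not
symmetric in general, and the decomposition is applied to the block as-is
(real parts taken), matching common practice; symmetrizing the block first
was tested and found to *break* the exact-inversion property below.  The
averaged directional sum is a Cartesian spring constant; it is halved so
the returned `k_r` is in the Amber convention `E = k_r (r − r_eq)²` used by
the frcmod writer.  Equilibrium values come from the reference geometry,
never from the Hessian.  Negative accumulated constants (possible at
non-stationary geometries) clamp to zero with a warning.

Angles *i–j–k* (apex *j*) project each arm block on the in-plane unit
vector perpendicular to that arm (`u_PA = û_N × û_ji`,
`u_PC = û_jk × û_N`) and combine the two measurements in series:

```
1/k_theta = 1/(R_ji^2 k_PA) + 1/(R_jk^2 k_PC)
```

Because each arm measurement sees the *full* angular spring, the series
combination of the two already halves the spring constant, so the value is
reported unchanged as the Amber-convention `k_theta`.

**Exactness analysis.**  The estimator is the exact inverse of a harmonic
generator in two regimes, and an approximation elsewhere:

* *Bond networks*: the interatomic block of a pair is touched only by the
  bond term on that pair (other bonds and atoms contribute to other
  blocks), so `k_r` recovery is exact for any geometry and any number of
  bonds.  The test suite verifies ~1e-15 relative recovery over
  randomized networks.
* *Isolated orthogonal-arm angles*: for a bare harmonic angle the arm
  measurement equals `k_s (1 − cosθ · R_arm/R_other)`; at θ = 90° the
  cosine term vanishes and recovery is exact (verified to ~1e-15).
* *General angles*: the estimator returns the closed form
  `k_s(1−cR₁/R₂)(1−cR₂/R₁) / ((1−cR₁/R₂)+(1−cR₂/R₁))` with `c = cosθ` —
  about 25% high at 104.5°.  A dedicated test asserts this closed form to
  1e-9, which pins the implementation even where the method itself is
  biased.
* *Coupled models*: when bonds and angles share atoms, the angle's rank-1
  block contribution has a component along the bond axis, eigenvectors
  mix, and both estimates acquire errors (about 0.2% on the bond and tens
  of percent on the angle in a water-like model).  Angles sharing an arm
  additionally pool their curvature: in the tetraammine demo complex each
  N–Cu–N estimate comes back near twice the generating constant.  These
  are intrinsic properties of the Seminario construction — widely
  considered acceptable for the stiff, enumeration-driven metal-center
  terms it is used for — not implementation artifacts.

Metal parameter enumeration: one bond per metal contact; one angle per
contact pair sharing the metal apex and per
(ligand-neighbor, ligand-atom, metal) triple.  Collinear triples (trans
pairs in square-planar complexes) are skipped with a warning since the
perpendicular projection is undefined at 180°.  Dihedrals through the
metal are assigned zero force constants (standard bonded-model practice);
ligand-internal dihedrals are expected from the ligand's own parameter
files.

Hessians load from the ORCA `$hessian` text dialect (hartree/bohr²,
converted by 627.509474/0.529177210903² ≈ 2240.88) or from plain
whitespace matrices (assumed already in kcal mol⁻¹ Å⁻² unless stated).
Inputs are symmetrized; asymmetry beyond 1e-3 relative is an error rather
than something to paper over.

## RESP charges

Merz–Kollman shells are placed at 1.4/1.6/1.8/2.0 × vdW radius at
1 point/Å² — the scheme's standard constants, exposed as arguments since
the workflow context ("recommended settings") leaves them implicit.
Sphere sampling uses a deterministic Fibonacci lattice: reproducible
without a seed, near-uniform, and free of the pole clustering of
latitude–longitude grids.  Points inside any other atom's sphere at the
same scale are discarded.

The fit minimizes the squared ESP residual plus the hyperbolic restraint
`a Σ (√(q²+b²) − b)` (b = 0.1 e) under a total-charge equality constraint,
by iterating the standard linearization (weights `a/√(q_prev²+b²)`) inside
a KKT solve until the largest charge change drops below 1e-8 e (cap 200
iterations, error on non-convergence).  The objective is convex, so the
iteration converges to the global constrained minimum.  With equivalence
groups the two-stage protocol runs: stage 1 (a = 0.0005) all atoms free,
stage 2 (a = 0.001) refits only grouped atoms with the rest frozen; with
no groups it degenerates to the single stage, which is also the chosen
default for metal sites.  Equivalence groups are explicit user input —
topological symmetry detection is out of scope.

One property worth stating precisely: a stronger restraint always lowers
the restraint *penalty* (a scalarization argument valid for any convex
fit), but it does **not** always lower the largest single charge — under a
total-charge constraint, shrinking most charges can push the remaining one
up slightly.  The tests therefore assert penalty monotonicity on every
random molecule and max-charge monotonicity on the two-atom dipole case,
where it is provable.

## Atom typing and parameter files

The metal and every first-shell partner receive fresh type codes (M1, M2,
… and Y1, Y2, …), one per atom, skipping collisions with existing types;
more than 99 fresh codes of one kind is an error.  All other atoms keep
their base types (ligand input or lowercase element symbols).  Metal
Lennard-Jones parameters come from a small packaged default list
(overridable); they are generic starting points, not fitted values.

frcmod files carry MASS/BOND/ANGLE/DIHE/NONBON sections with fixed-width
4-decimal formatting.  Force constants are stored exactly as used in
`E = k (x − x₀)²` — no half-k convention is applied at write time, so the
writer and the Seminario output agree by construction.  Write→read round
trips preserve every parameter to 1e-4 (the formatting precision).

## Solvent boxes and MD inputs

The box edge is the solute extent plus twice `margin`.  The target
molecule count is `ρ V N_A / M` from the template's experimental density
(water 0.997, chloroform 1.489, dichloromethane 1.327 g cm⁻³).  Copies
sit on a simple-cubic lattice with two alternating orientations in a
checkerboard pattern; a seeded search over random orientation pairs
maximizes the minimum interatomic clearance between lattice neighbors.
This matters because a naive lattice of identically oriented waters cannot
reach the experimental density without violating a 2.0 Å clash threshold,
while a good checkerboard pair clears it with margin.  Positions are
jittered within the spare clearance; any copy still violating `min_dist`
against the solute or a previous copy is removed.  If no orientation pair
passes at the ideal lattice constant, the lattice coarsens one step at a
time, trading density for the hard minimum-distance invariant — so
packed densities are geometric targets that can fall short at awkward box
sizes, and are in any case starting densities, not equilibrated ones.
Counterions (one per charge unit needed for neutrality) go to the box
faces farthest from the solute, with a warning when the ion charge cannot
exactly neutralize.

The equilibration ladder (restrained minimization, stepwise NVT heating
10→300 K, one cool/reheat cycle, a short NPT relaxation) is a configurable
stand-in template, clearly replaceable via `sim_protocol()`; the
production deck encodes NVT at 300 K and a step count equal to 100 ns at
the configured timestep (50,000,000 steps at 2 fs), all overridable.

## Trajectory clustering

Frames are aligned by Kabsch superposition computed on a user-supplied
atom index list (1-based, matching PDB serials; at least three
non-collinear atoms) and applied to all atoms.  Distances are heavy-atom
RMSDs.  Under the `kmeans` name the package runs PAM-style k-medoids on
the precomputed distance matrix — centroid k-means is ill-defined on an
RMSD metric without iterative re-alignment — with farthest-point seeding
from a seeded start and alternating assignment/update sweeps whose
objective is non-increasing.  `hierarchical` is average-linkage
agglomeration cut at k; `dbscan` is the standard density clustering;
`dpeaks` implements the cutoff-kernel density-peaks variant (local density
ρ within `eps`, separation δ to the nearest denser frame, top-k ρ·δ as
centers) — the kernel choice is stated here because tool conventions
differ.  Representatives are cluster medoids.  Ranking sorts clusters by
supplied single-point energies (ascending, relative to the minimum), with
ties broken by population (larger first), then cluster id.  Default
cluster count is 10, matching common practice for conformer searches;
every stochastic step takes an explicit seed (default 2023).

## Synthetic fixtures: what they do and do not show

`analytic_hessian()` builds exact second derivatives of
`E = Σ k_r (r−r_eq)² + Σ k_θ (θ−θ_eq)²` at the model's equilibrium (the
outer-product form is exact only there, so off-equilibrium geometries are
rejected), cross-validated against central finite differences (step
1e-5 Å) to 1e-6 relative.  `two_basin_trajectory()` draws Gaussian
perturbations around two reference geometries differing by one displaced
peripheral atom (defaults: 50 frames per basin, 3 Å displacement, 0.1 Å
noise), carrying ground-truth labels.

These fixtures emulate the *mathematical* structure the algorithms
consume — harmonic curvature, Coulombic grids, well-separated conformer
basins — not the physics of real systems: no anharmonicity, no
polarization or charge transfer at the metal, no correlated solvent
motion, no basin overlap or transition frames.  Passing tests therefore
demonstrate that the implementations invert their own model classes
correctly and reproduce closed-form oracles; they do not certify accuracy
of bonded-model parameters for any particular real complex, which depends
on the quality of the quantum Hessian, ESP and the bonded-model
approximation itself.

## Problem sizes and tolerances

The test and acceptance runs use: 25 random bond-network fixtures (4–9
atoms) and 25 orthogonal-angle fixtures for Seminario recovery at 1e-6
relative (observed ~1e-15); 20 random 2–4-atom molecules with ≥300-point
grids for RESP recovery at 1e-4 e and charge conservation at 1e-8 e; 200
random geometries against the union-find fragmentation oracle; a
100-frame two-basin trajectory for clustering (ARI exactly 1 required for
all four methods); and a 17-atom complex in a ~270-water box for the
end-to-end run.  These sizes keep the full suite to seconds while leaving
each property over-determined.
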